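# Caller VCF dialect mapping (our convention; documented here because the
# upstream tools do not share a single support/depth encoding):
#   sniffles: support = INFO/RE (fallback FORMAT/DV); depth = FORMAT DV + DR
#   nanovar:  support = INFO/SR;                      depth = INFO/DP
#   nanosv:   support = FORMAT/DV;                    depth = FORMAT DV + DR
#   truth:    support = INFO/SUPPORT;                 depth = INFO/DP
#   other:    support = INFO SUPPORT|RE|SR;           depth = INFO/DP or NA

.info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

.fmt_field <- function(vcf, key) {
  gt <- tryCatch(vcfR::extract.gt(vcf, element = key, as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(gt)) return(rep(NA_real_, nrow(vcf@fix)))
  as.numeric(gt[, 1])
}

#' Read a caller VCF into the internal SV model
#'
#' Normalizes one caller's dialect: 1-based POS becomes the 0-based start;
#' negative SVLEN (the deletion convention) is taken as an absolute value;
#' a missing SVLEN is recovered from END (`svlen = END - POS + 1`); INS end
#' coordinates are rebuilt as `start + svlen` (synthetic interval);
#' breakend/translocation and other non-canonical records are dropped with
#' a reported count; records without SVTYPE are skipped with a warning.
#' Support and depth come from the per-caller field mapping documented in
#' the source.
#'
#' @param path VCF file.
#' @param caller_id one of `sniffles`, `nanovar`, `nanosv`, `truth`,
#'   `other`.
#' @param sample_id sample identity to stamp on the calls.
#' @return `sv_calls` data frame.
#' @export
read_caller_vcf <- function(path, caller_id, sample_id) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparseable VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_sv_calls())
  info <- fix[, "INFO"]
  svtype <- .info_field(info, "SVTYPE")
  if (anyNA(svtype)) {
    warning(sum(is.na(svtype)), " record(s) without SVTYPE skipped")
  }
  canonical <- !is.na(svtype) & svtype %in% .SV_TYPES
  n_drop <- sum(!is.na(svtype) & !svtype %in% .SV_TYPES)
  if (n_drop > 0)
    message(n_drop, " non-canonical record(s) (BND/TRA/...) dropped")
  pos <- as.numeric(fix[, "POS"])
  svlen <- abs(as.numeric(.info_field(info, "SVLEN")))
  endf <- as.numeric(.info_field(info, "END"))
  svlen <- ifelse(is.na(svlen), endf - pos + 1, svlen)
  support <- switch(caller_id,
    sniffles = {
      re <- as.numeric(.info_field(info, "RE"))
      ifelse(is.na(re), .fmt_field(vcf, "DV"), re)
    },
    nanovar = as.numeric(.info_field(info, "SR")),
    nanosv = .fmt_field(vcf, "DV"),
    truth = as.numeric(.info_field(info, "SUPPORT")),
    {
      s <- as.numeric(.info_field(info, "SUPPORT"))
      s <- ifelse(is.na(s), as.numeric(.info_field(info, "RE")), s)
      ifelse(is.na(s), as.numeric(.info_field(info, "SR")), s)
    })
  depth <- switch(caller_id,
    sniffles = .fmt_field(vcf, "DV") + .fmt_field(vcf, "DR"),
    nanovar = as.numeric(.info_field(info, "DP")),
    nanosv = .fmt_field(vcf, "DV") + .fmt_field(vcf, "DR"),
    as.numeric(.info_field(info, "DP")))
  keep <- canonical & !is.na(svlen) & svlen >= 1
  if (!any(keep)) return(empty_sv_calls())
  sv_calls(sample_id = sample_id, caller_id = caller_id,
           sv_type = svtype[keep], chrom = fix[keep, "CHROM"],
           start = pos[keep] - 1, svlen = svlen[keep],
           support_reads = ifelse(is.na(support[keep]), 0, support[keep]),
           site_depth = depth[keep])
}

.vcf_header <- function(contigs, info_lines, format_lines, samples) {
  c("##fileformat=VCFv4.2",
    "##source=svpop",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    info_lines, format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
}

#' Write SV calls as a caller-dialect VCF
#'
#' One sample per file. `END` is written as `POS + svlen - 1` for
#' DEL/DUP/INV and as `POS` for INS; SVLEN is negative for deletions in the
#' sniffles dialect.
#'
#' @param calls `sv_calls` for one sample and one caller.
#' @param path output file.
#' @param contigs named vector of chromosome lengths; inferred from the
#'   calls when omitted.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path, contigs = NULL) {
  caller <- unique(calls$caller_id)
  if (length(caller) > 1) stop("calls must come from a single caller")
  if (length(caller) == 0) caller <- "other"
  sample <- unique(calls$sample_id)
  if (length(sample) > 1) stop("calls must come from a single sample")
  if (length(sample) == 0) sample <- "sample"
  if (is.null(contigs)) {
    contigs <- tapply(calls$end + 1000, calls$chrom, max)
  }
  info_lines <- c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">')
  fmt <- "GT"
  if (caller == "sniffles") {
    info_lines <- c(info_lines,
      '##INFO=<ID=RE,Number=1,Type=Integer,Description="Read evidence">')
    fmt <- "GT:DR:DV"
  } else if (caller == "nanovar") {
    info_lines <- c(info_lines,
      '##INFO=<ID=SR,Number=1,Type=Integer,Description="Supporting reads">',
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">')
  } else if (caller == "nanosv") {
    fmt <- "GT:DV:DR"
  } else {
    info_lines <- c(info_lines,
      '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting reads">',
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">')
  }
  format_lines <- c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (grepl("DV", fmt)) c(
      '##FORMAT=<ID=DR,Number=1,Type=Integer,Description="Reference reads">',
      '##FORMAT=<ID=DV,Number=1,Type=Integer,Description="Variant reads">'))
  hdr <- .vcf_header(contigs, info_lines, format_lines, sample)
  pos <- calls$start + 1
  end1 <- ifelse(calls$sv_type == "INS", pos, pos + calls$svlen - 1)
  svlen_out <- calls$svlen
  if (caller == "sniffles")
    svlen_out <- ifelse(calls$sv_type == "DEL", -calls$svlen, calls$svlen)
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", calls$sv_type,
                  as.integer(svlen_out), as.integer(end1))
  dr <- ifelse(is.na(calls$site_depth), 0,
               calls$site_depth - calls$support_reads)
  sup <- as.integer(calls$support_reads)
  if (caller == "sniffles") {
    info <- paste0(info, sprintf(";RE=%d", sup))
    smp <- sprintf("./.:%d:%d", as.integer(dr), sup)
  } else if (caller == "nanovar") {
    info <- paste0(info, sprintf(";SR=%d;DP=%s", sup,
                                 ifelse(is.na(calls$site_depth), ".",
                                        as.character(as.integer(calls$site_depth)))))
    smp <- "./."
  } else if (caller == "nanosv") {
    smp <- sprintf("./.:%d:%d", sup, as.integer(dr))
  } else {
    info <- paste0(info, sprintf(";SUPPORT=%d;DP=%s", sup,
                                 ifelse(is.na(calls$site_depth), ".",
                                        as.character(as.integer(calls$site_depth)))))
    smp <- "./."
  }
  body <- paste(calls$chrom, as.integer(pos),
                sprintf("%s_%05d", toupper(substr(caller, 1, 3)),
                        seq_len(nrow(calls))),
                "N", paste0("<", calls$sv_type, ">"), ".", "PASS",
                info, fmt, smp, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a population SV set as a multi-sample VCF
#'
#' INFO carries SVTYPE, SVLEN, END, AC, AN, AF; FORMAT carries GT. For INS,
#' `END` follows VCF convention (`POS`) and the synthetic end
#' (`start + svlen`, 1-based inclusive) is preserved in `INSEND`.
#'
#' @param popset an `sv_popset` from [merge_population()].
#' @param path output file.
#' @param contigs optional named chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(popset, path, contigs = NULL) {
  svs <- popset$svs
  if (anyDuplicated(svs$sv_id)) stop("duplicate SV ids")
  G <- popset$genotypes
  if (is.null(contigs)) contigs <- tapply(svs$end + 1000, svs$chrom, max)
  info_lines <- c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=INSEND,Number=1,Type=Integer,Description="Synthetic INS end (start + SVLEN)">',
    '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alt allele count">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total alleles">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alt allele frequency">')
  format_lines <- '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  hdr <- .vcf_header(contigs, info_lines, format_lines, popset$samples)
  pos <- svs$start + 1
  is_ins <- svs$sv_type == "INS"
  end1 <- ifelse(is_ins, pos, pos + svs$svlen - 1)
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", svs$sv_type,
                  as.integer(svs$svlen), as.integer(end1))
  info[is_ins] <- paste0(info[is_ins],
                         sprintf(";INSEND=%d", as.integer(pos[is_ins] + svs$svlen[is_ins] - 1)))
  info <- paste0(info, sprintf(";AC=%d;AN=%d;AF=%s", svs$AC, svs$AN,
                               sprintf("%.8g", svs$AF)))
  gtchar <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  gt[ok] <- gtchar[G[ok] + 1]
  body <- paste(svs$chrom, as.integer(pos), svs$sv_id, "N",
                paste0("<", svs$sv_type, ">"), ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a population VCF written by [write_population_vcf()]
#'
#' Rebuilds the `sv_popset`: dosages from GT, allele statistics recomputed
#' from the genotypes, categories re-derived.
#'
#' @param path VCF file.
#' @return `sv_popset`.
#' @export
read_population_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparseable VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcf@fix
  samples <- colnames(vcf@gt)[-1]
  if (is.null(fix) || nrow(fix) == 0) {
    return(structure(list(
      svs = data.frame(sv_id = character(), sv_type = character(),
                       chrom = character(), start = numeric(),
                       end = numeric(), svlen = numeric(),
                       n_detected = integer(), AC = integer(),
                       AN = integer(), AF = numeric(), MAF = numeric(),
                       category = character(), stringsAsFactors = FALSE),
      genotypes = matrix(integer(), nrow = length(samples), ncol = 0,
                         dimnames = list(samples, NULL)),
      samples = samples), class = "sv_popset"))
  }
  info <- fix[, "INFO"]
  svtype <- .info_field(info, "SVTYPE")
  svlen <- abs(as.numeric(.info_field(info, "SVLEN")))
  start <- as.numeric(fix[, "POS"]) - 1
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(fix),
                dimnames = list(samples, unname(fix[, "ID"])))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (s in seq_along(samples))
    dos[s, ] <- unname(map[gtm[, samples[s]]])
  svs <- data.frame(sv_id = fix[, "ID"], sv_type = svtype, chrom = fix[, "CHROM"],
                    start = start, end = start + svlen, svlen = svlen,
                    n_detected = NA_integer_, stringsAsFactors = FALSE)
  svs$AC <- as.integer(colSums(dos, na.rm = TRUE))
  svs$AN <- as.integer(2L * colSums(!is.na(dos)))
  svs$AF <- ifelse(svs$AN > 0, svs$AC / svs$AN, NA_real_)
  svs$MAF <- pmin(svs$AF, 1 - svs$AF)
  svs$category <- NA_character_
  poly <- !is.na(svs$AF) & svs$AC > 0
  svs$category[poly] <- classify_af(svs$AC[poly], svs$AN[poly])
  rownames(svs) <- NULL
  structure(list(svs = svs, genotypes = dos, samples = samples),
            class = "sv_popset")
}

#' Read a region mask BED
#'
#' @param path BED 3+ file (0-based half-open, BED native).
#' @param label mask label (`centromere`, `gap`, `highdepth`).
#' @return data frame `label`, `chrom`, `start`, `end`.
#' @export
read_region_bed <- function(path, label = "gap") {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(label = label,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write region masks as BED
#'
#' @param masks mask data frame (`chrom`, `start`, `end`; one label).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(masks, path) {
  write.table(masks[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein-coding gene models from a GTF
#'
#' Ensembl-dialect GTF with gene/CDS/UTR features. Promoters are the 1 kb
#' region directly preceding the transcription start site, strand-aware,
#' clipped at position 0.
#'
#' @param path GTF file.
#' @return gene-model container: list with data frames `genes` (`gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `promoter_start`, `promoter_end`),
#'   `cds` and `utr` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF '", path, "': ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_gene <- type == "gene"
  if ("gene_biotype" %in% names(md))
    is_gene <- is_gene & (is.na(md$gene_biotype) |
                          md$gene_biotype == "protein_coding")
  gsub_ <- gr[is_gene]
  strand <- as.character(GenomicRanges::strand(gsub_))
  gs <- GenomicRanges::start(gsub_) - 1
  ge <- GenomicRanges::end(gsub_)
  prom_s <- ifelse(strand == "+", pmax(0, gs - 1000), ge)
  prom_e <- ifelse(strand == "+", gs, ge + 1000)
  genes <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gsub_)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gsub_)),
    strand = strand, start = gs, end = ge,
    promoter_start = prom_s, promoter_end = prom_e,
    stringsAsFactors = FALSE)
  grab <- function(sel, side = NULL) {
    sub <- gr[sel]
    d <- data.frame(gene_id = as.character(S4Vectors::mcols(sub)$gene_id),
                    chrom = as.character(GenomicRanges::seqnames(sub)),
                    start = GenomicRanges::start(sub) - 1,
                    end = GenomicRanges::end(sub),
                    stringsAsFactors = FALSE)
    if (!is.null(side)) d$side <- rep(side, nrow(d))
    d
  }
  cds <- grab(type == "CDS")
  utr <- rbind(grab(type == "five_prime_utr", "5"),
               grab(type == "three_prime_utr", "3"))
  if (nrow(utr) == 0 && any(type == "UTR")) utr <- grab(type == "UTR", NA)
  list(genes = genes, cds = cds, utr = utr)
}

#' Write gene models as Ensembl-dialect GTF
#'
#' @param genes gene-model container (see [read_gene_models()]).
#' @param path output GTF file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  attr_of <- function(gid) sprintf(
    'gene_id "%s"; transcript_id "%s.t1"; gene_biotype "protein_coding";',
    gid, gid)
  line <- function(chrom, feat, s0, e0, strand, gid)
    paste(chrom, "svpop", feat, s0 + 1, e0, ".", strand, ".", attr_of(gid),
          sep = "\t")
  g <- genes$genes
  out <- character()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    out <- c(out,
             line(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i], gid),
             line(g$chrom[i], "transcript", g$start[i], g$end[i], g$strand[i], gid))
    cds <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(cds)))
      out <- c(out, line(cds$chrom[k], "CDS", cds$start[k], cds$end[k],
                         g$strand[i], gid))
    utr <- genes$utr[genes$utr$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(utr)))
      out <- c(out, line(utr$chrom[k],
                         if (identical(utr$side[k], "3")) "three_prime_utr"
                         else "five_prime_utr",
                         utr$start[k], utr$end[k], g$strand[i], gid))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an external SV reference table (TSV/BED-like)
#'
#' Expects columns `chrom`, `start`, `end`, `type` and optionally `svlen`
#' (tab-separated, header line). Types are normalized via
#' [normalize_external_sv()].
#'
#' @param path TSV file.
#' @return normalized `sv_calls` reference table.
#' @export
read_external_sv_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  normalize_external_sv(df)
}
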