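# Gene-model container: list(genes, cds, utr) of 0-based half-open interval
# data frames. `genes` has gene_id, chrom, strand, start, end,
# promoter_start, promoter_end; `cds`/`utr` have gene_id, chrom, start, end
# (utr also carries `side` in {"5","3"}).

.gr0 <- function(chrom, start, end, seqlevels = NULL) {
  if (!is.null(seqlevels)) chrom <- factor(chrom, levels = seqlevels)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

.sv_gr <- function(svs) .gr0(svs$chrom, svs$start, svs$end)

#' Predicted loss-of-function and whole-gene impact classification
#'
#' Coding impact per SV: a DEL overlapping at least one CDS is pLoF; an INS
#' whose start lies strictly inside a CDS is pLoF; a DUP or INV partially
#' overlapping at least one CDS of a gene it does not fully contain is pLoF
#' for that gene; a DUP/INV containing an entire gene span is WDUP/WINV for
#' that gene (not gene-disruptive). A single DUP/INV may be WDUP/WINV for
#' one gene and pLoF for another; the `impact` field then reports pLoF and
#' both gene lists are returned.
#'
#' @param svs SV table (`sv_calls` columns or a popset `svs` table with
#'   `sv_type`, `chrom`, `start`, `end`).
#' @param genes gene models from [read_gene_models()] or
#'   [simulate_genome()].
#' @return data frame, one row per SV: `impact` in
#'   `{pLoF, WDUP, WINV, none}`, `plof_genes`, `whole_genes` (comma-joined
#'   gene ids; empty string when none).
#' @export
classify_coding_impact <- function(svs, genes) {
  n <- nrow(svs)
  plof <- vector("list", n)
  whole <- vector("list", n)
  if (n > 0 && nrow(genes$cds) > 0) {
    svg <- .sv_gr(svs)
    cdsg <- .gr0(genes$cds$chrom, genes$cds$start, genes$cds$end)
    ov <- GenomicRanges::findOverlaps(svg, cdsg)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    gid <- genes$cds$gene_id[sh]
    gtab <- genes$genes
    gspan_start <- gtab$start[match(gid, gtab$gene_id)]
    gspan_end <- gtab$end[match(gid, gtab$gene_id)]
    type <- svs$sv_type[qh]
    contains_gene <- svs$start[qh] <= gspan_start & svs$end[qh] >= gspan_end
    ins_inside <- type == "INS" &
      svs$start[qh] > genes$cds$start[sh] & svs$start[qh] < genes$cds$end[sh]
    is_plof <- (type == "DEL") |
      ins_inside |
      (type %in% c("DUP", "INV") & !contains_gene)
    for (k in which(is_plof)) plof[[qh[k]]] <- c(plof[[qh[k]]], gid[k])
    # whole-gene containment checked against all genes, not only CDS hits
    dupinv <- which(svs$sv_type %in% c("DUP", "INV"))
    if (length(dupinv) && nrow(gtab) > 0) {
      gg <- .gr0(gtab$chrom, gtab$start, gtab$end)
      ov2 <- GenomicRanges::findOverlaps(.sv_gr(svs[dupinv, , drop = FALSE]),
                                         gg, type = "any")
      q2 <- dupinv[S4Vectors::queryHits(ov2)]; s2 <- S4Vectors::subjectHits(ov2)
      cont <- svs$start[q2] <= gtab$start[s2] & svs$end[q2] >= gtab$end[s2]
      for (k in which(cont)) whole[[q2[k]]] <- c(whole[[q2[k]]], gtab$gene_id[s2[k]])
    }
  }
  impact <- rep("none", n)
  has_whole <- lengths(whole) > 0
  impact[has_whole] <- ifelse(svs$sv_type[has_whole] == "DUP", "WDUP", "WINV")
  impact[lengths(plof) > 0] <- "pLoF"
  data.frame(
    impact = impact,
    plof_genes = vapply(plof, function(g) paste(sort(unique(g)), collapse = ","), ""),
    whole_genes = vapply(whole, function(g) paste(sort(unique(g)), collapse = ","), ""),
    stringsAsFactors = FALSE)
}

# TRUE where the point p (0-based position) lies in some interval of df
.point_in <- function(chrom, p, df) {
  if (nrow(df) == 0) return(rep(FALSE, length(p)))
  pg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(p + 1, p + 1))
  ig <- .gr0(df$chrom, df$start, df$end)
  IRanges::overlapsAny(pg, ig)
}

.intersects_any <- function(svs, df) {
  if (nrow(df) == 0 || nrow(svs) == 0) return(rep(FALSE, nrow(svs)))
  IRanges::overlapsAny(.sv_gr(svs), .gr0(df$chrom, df$start, df$end))
}

#' Gene-feature assignment
#'
#' One feature label per SV with precedence CDS > UTR > promoter > intron >
#' intergenic: CDS if the SV intersects any CDS interval; UTR if a
#' breakpoint (start or end) lies in a 5' or 3' UTR and the SV does not
#' intersect a CDS; promoter if a breakpoint lies in a promoter (the 1 kb
#' strand-aware region preceding the TSS) and the SV intersects neither CDS
#' nor UTR; intron if both breakpoints fall within one gene's span;
#' intergenic otherwise. A breakpoint at position p is "in" `[s, e)` when
#' `s <= p < e`.
#'
#' @inheritParams classify_coding_impact
#' @return character vector of features, one per SV.
#' @export
assign_gene_feature <- function(svs, genes) {
  n <- nrow(svs)
  if (n == 0) return(character())
  gtab <- genes$genes
  prom <- data.frame(gene_id = gtab$gene_id, chrom = gtab$chrom,
                     start = gtab$promoter_start, end = gtab$promoter_end,
                     stringsAsFactors = FALSE)
  in_cds <- .intersects_any(svs, genes$cds)
  in_utr <- .intersects_any(svs, genes$utr)
  bp_utr <- .point_in(svs$chrom, svs$start, genes$utr) |
    .point_in(svs$chrom, svs$end, genes$utr)
  bp_prom <- .point_in(svs$chrom, svs$start, prom) |
    .point_in(svs$chrom, svs$end, prom)
  both_in_gene <- rep(FALSE, n)
  if (nrow(gtab) > 0) {
    gg <- .gr0(gtab$chrom, gtab$start, gtab$end)
    s_in <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(svs$start + 1, svs$start + 1)), gg)
    e_in <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(svs$end + 1, svs$end + 1)), gg)
    # both breakpoints in the same gene (end breakpoint may equal gene end,
    # which in half-open coordinates lies one base past the last gene base;
    # we require the position itself inside the span)
    key_s <- paste(S4Vectors::queryHits(s_in), S4Vectors::subjectHits(s_in))
    key_e <- paste(S4Vectors::queryHits(e_in), S4Vectors::subjectHits(e_in))
    both <- intersect(key_s, key_e)
    idx <- as.integer(sub(" .*", "", both))
    both_in_gene[unique(idx)] <- TRUE
  }
  feature <- rep("intergenic", n)
  feature[both_in_gene] <- "intron"
  feature[bp_prom & !in_cds & !in_utr] <- "promoter"
  feature[bp_utr & !in_cds] <- "UTR"
  feature[in_cds] <- "CDS"
  feature
}

#' Repeat-content classification
#'
#' Per-family repeat coverage within the SV interval (overlapping intervals
#' of one family are unioned first). The family whose covered bases exceed
#' half the SV length wins; a winning tandem-repeat annotation with unit
#' length >= 7 bp is labelled `VNTR`; otherwise `family:<name>`; `none`
#' when no family exceeds half.
#'
#' @param svs SV table.
#' @param repeats data frame `chrom`, `start`, `end` (0-based half-open),
#'   `family`, `unit_len` (`NA` for non-tandem annotations), e.g. parsed
#'   from RepeatMasker/TRF output.
#' @return character vector of repeat classes.
#' @export
classify_repeat <- function(svs, repeats) {
  n <- nrow(svs)
  if (n == 0) return(character())
  out <- rep("none", n)
  if (is.null(repeats) || nrow(repeats) == 0) return(out)
  rep2 <- repeats
  tand <- !is.na(rep2$unit_len) & rep2$unit_len >= 7
  rep2$family[tand] <- "VNTR"
  svg <- .sv_gr(svs)
  rg <- .gr0(rep2$chrom, rep2$start, rep2$end)
  ov <- GenomicRanges::findOverlaps(svg, rg)
  if (length(ov) == 0) return(out)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  for (i in unique(qh)) {
    rsub <- rep2[sh[qh == i], , drop = FALSE]
    rsub$start <- pmax(rsub$start, svs$start[i])
    rsub$end <- pmin(rsub$end, svs$end[i])
    cov <- vapply(split(rsub, rsub$family), function(d) {
      merged <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      sum(IRanges::width(merged))
    }, numeric(1))
    if (max(cov) > svs$svlen[i] / 2) {
      fam <- names(cov)[which.max(cov)]
      out[i] <- if (fam == "VNTR") "VNTR" else paste0("family:", fam)
    }
  }
  out
}

#' Feature enrichment per allele-frequency category
#'
#' For each (category, feature) cell of a count table, a 2x2 contingency
#' table (in-category & in-feature vs the rest of the population) is tested
#' with a two-sided Fisher exact test; p-values are Benjamini-Hochberg
#' adjusted across all tested cells. The enrichment universe is the whole
#' SV population (all table cells).
#'
#' @param counts integer matrix, categories x features.
#' @return data frame with `category`, `feature`, `odds_ratio`, `p`, `q`
#'   (`NA` for cells with a zero margin).
#' @export
feature_enrichment <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  rows <- rownames(counts); cols <- colnames(counts)
  res <- expand.grid(category = rows, feature = cols,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$odds_ratio <- NA_real_; res$p <- NA_real_
  for (k in seq_len(nrow(res))) {
    i <- res$category[k]; j <- res$feature[k]
    a <- counts[i, j]
    b <- sum(counts[i, ]) - a
    c_ <- sum(counts[, j]) - a
    d <- total - a - b - c_
    if (sum(counts[i, ]) == 0 || sum(counts[, j]) == 0) next
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    res$odds_ratio[k] <- unname(ft$estimate)
    res$p[k] <- ft$p.value
  }
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res
}

#' Annotate a population SV set
#'
#' Convenience wrapper combining impact, feature and repeat classification
#' into one table, one row per SV.
#'
#' @param popset an `sv_popset` from [merge_population()].
#' @param genes gene models.
#' @param repeats optional repeat annotation table (see [classify_repeat()]).
#' @return data frame keyed by `sv_id`.
#' @export
annotate_popset <- function(popset, genes, repeats = NULL) {
  svs <- popset$svs
  imp <- classify_coding_impact(svs, genes)
  data.frame(sv_id = svs$sv_id,
             sv_type = svs$sv_type,
             category = svs$category,
             feature = assign_gene_feature(svs, genes),
             impact = imp$impact,
             plof_genes = imp$plof_genes,
             whole_genes = imp$whole_genes,
             repeat_class = if (is.null(repeats)) NA_character_
                            else classify_repeat(svs, repeats),
             stringsAsFactors = FALSE)
}
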