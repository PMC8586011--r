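#' Simulation parameters
#'
#' Defaults emulate the per-sample SV landscape of a long-read population
#' study: a DEL/INS-dominated type mix (44.4/53.8/1.4/0.4%), a bimodal
#' indel length distribution with peaks near 300 bp (SINE-scale) and 6 kb
#' (LINE-scale) over a lognormal body, a singleton-heavy site-frequency
#' spectrum (Beta(0.3, 2) truncated to at least one carrier), and
#' Balding-Nichols subpopulation divergence.
#'
#' @param n_samples number of diploid samples.
#' @param n_svs number of truth SV loci.
#' @param type_mix named fractions over DEL/INS/DUP/INV (sums to 1).
#' @param length_model mixture weights and component parameters (bp).
#' @param sfs ancestral allele-frequency model: `list(kind = "beta", shape1,
#'   shape2)`, `list(kind = "uniform", min, max)` or
#'   `list(kind = "fixed", af = <vector>)`.
#' @param subpops data frame `group`, `n`, `F` (Balding-Nichols F per
#'   subpopulation; 0 = no divergence). Defaults to one panmictic group of
#'   `n_samples`.
#' @param depth mean sequencing depth (fold).
#' @param n_plof number of planted pLoF deletions overlapping a CDS.
#' @param n_diff number of planted differentiated loci.
#' @param diff_F target fixation index at planted differentiated loci: the
#'   focal subpopulation's frequency is displaced from the ancestral value
#'   by the deterministic amount that sets the true focal-vs-ancestral
#'   F_ST to `diff_F`, modelling local adaptation on one population's
#'   branch (the other groups keep their neutral Balding-Nichols draws).
#' @param diff_group subpopulation carrying the planted divergence
#'   (default: the first subpopulation).
#' @param seed integer RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 50, n_svs = 5000,
                       type_mix = c(DEL = 0.444, INS = 0.538,
                                    DUP = 0.014, INV = 0.004),
                       length_model = list(
                         weights = c(body = 0.55, alu = 0.35,
                                     line = 0.07, tail = 0.03),
                         body_meanlog = log(120), body_sdlog = 0.9,
                         alu_mean = 300, alu_sd = 30,
                         line_mean = 6000, line_sd = 600,
                         tail_meanlog = log(2e4), tail_sdlog = 0.8,
                         min_len = 50, max_len = 1e5),
                       sfs = list(kind = "beta", shape1 = 0.3, shape2 = 2.0),
                       subpops = NULL, depth = 15,
                       n_plof = 0, n_diff = 0, diff_F = 0.3,
                       diff_group = NULL, seed = 1) {
  if (abs(sum(type_mix) - 1) > 1e-6) stop("type_mix must sum to 1")
  if (is.null(subpops))
    subpops <- data.frame(group = "pop1", n = n_samples, F = 0,
                          stringsAsFactors = FALSE)
  if (sum(subpops$n) != n_samples)
    stop("subpop sizes must sum to n_samples")
  if (any(subpops$F < 0 | subpops$F >= 1)) stop("F must be in [0, 1)")
  if (is.null(diff_group)) diff_group <- subpops$group[1]
  structure(list(n_samples = n_samples, n_svs = n_svs, type_mix = type_mix,
                 length_model = length_model, sfs = sfs, subpops = subpops,
                 depth = depth, n_plof = n_plof, n_diff = n_diff,
                 diff_F = diff_F, diff_group = diff_group, seed = seed),
            class = "sim_params")
}

#' Default emulated caller profiles
#'
#' Three imperfect callers with decreasing sensitivity and increasing
#' breakpoint jitter and false-positive load, mirroring the disagreement
#' seen between long-read SV callers: sensitivities 0.95/0.90/0.85,
#' breakpoint jitter SD 10/20/30 bp, false calls per genome 300/500/800.
#' Support counts follow Binomial(depth, 0.5) for heterozygotes and
#' Binomial(depth, 1.0) for homozygotes.
#'
#' @return named list of profiles (`caller_id`, `sensitivity` per type,
#'   `breakpoint_jitter_sd`, `length_jitter_cv`, `fp_rate`).
#' @export
default_caller_profiles <- function() {
  mk <- function(id, sens, sd, fp)
    list(caller_id = id,
         sensitivity = c(DEL = sens, INS = sens, DUP = sens, INV = sens),
         breakpoint_jitter_sd = sd, length_jitter_cv = 0.02, fp_rate = fp)
  list(sniffles = mk("sniffles", 0.95, 10, 300),
       nanovar = mk("nanovar", 0.90, 20, 500),
       nanosv = mk("nanosv", 0.85, 30, 800))
}

#' Identity (noise-free) caller profile
#'
#' Sensitivity 1, zero jitter, zero false positives: emitted calls equal the
#' truth carriers exactly.
#'
#' @param caller_id caller identity for the emitted calls.
#' @return profile list as in [default_caller_profiles()].
#' @export
identity_caller_profile <- function(caller_id = "sniffles") {
  list(caller_id = caller_id,
       sensitivity = c(DEL = 1, INS = 1, DUP = 1, INV = 1),
       breakpoint_jitter_sd = 0, length_jitter_cv = 0, fp_rate = 0)
}

#' Simulate a toy genome: chromosomes, arms, masks, gene models
#'
#' Chromosomes with a central centromere, a few assembly-gap and high-depth
#' mask intervals, and non-overlapping protein-coding gene models (5' UTR,
#' CDS exons, 3' UTR, strand-aware 1 kb promoter) placed outside all masks.
#'
#' @param n_chroms,chrom_len number and length (bp, >= 1 Mb) of
#'   chromosomes.
#' @param n_genes total number of genes.
#' @param centromere_frac centromere width as a fraction of the chromosome.
#' @param n_gaps gap intervals per chromosome.
#' @param gap_len gap width in bp.
#' @param seed integer RNG seed.
#' @return list of class `sim_genome`: `chrom_len` (named), `arms`, `masks`,
#'   `genes` (gene-model container as from [read_gene_models()]).
#' @export
simulate_genome <- function(n_chroms = 3, chrom_len = 1e7, n_genes = 60,
                            centromere_frac = 0.1, n_gaps = 2,
                            gap_len = 5e4, seed = 1) {
  if (chrom_len < 1e6) stop("chromosome length must be >= 1 Mb")
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))
  clen <- stats::setNames(rep(chrom_len, n_chroms), chroms)
  cen_s <- round(chrom_len * (0.5 - centromere_frac / 2))
  cen_e <- round(chrom_len * (0.5 + centromere_frac / 2))
  arms <- data.frame(chrom = chroms, p_start = 0, cen_start = cen_s,
                     cen_end = cen_e, q_end = chrom_len,
                     stringsAsFactors = FALSE)
  masks <- data.frame(label = "centromere", chrom = chroms,
                      start = cen_s, end = cen_e, stringsAsFactors = FALSE)
  for (ch in chroms) {
    for (k in seq_len(n_gaps)) {
      repeat {
        s <- floor(runif(1, 0, chrom_len - gap_len))
        if (s + gap_len <= cen_s || s >= cen_e) break
      }
      masks <- rbind(masks, data.frame(label = if (k == 1) "gap" else "highdepth",
                                       chrom = ch, start = s, end = s + gap_len,
                                       stringsAsFactors = FALSE))
    }
  }
  genes <- .place_genes(chroms, chrom_len, masks, n_genes)
  structure(list(chrom_len = clen, arms = arms, masks = masks, genes = genes,
                 seed = seed), class = "sim_genome")
}

.place_genes <- function(chroms, chrom_len, masks, n_genes) {
  per_chrom <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1)))
  gtab <- list(); cds <- list(); utr <- list()
  gid <- 0L
  mask_gr <- .gr0(masks$chrom, masks$start, masks$end, chroms)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    occupied <- .gr0(character(), numeric(), numeric(), chroms)
    placed <- 0L; tries <- 0L
    while (placed < per_chrom[ci] && tries < 5000L) {
      tries <- tries + 1L
      glen <- round(runif(1, 8000, 20000))
      gs <- floor(runif(1, 1000, chrom_len - glen - 1000))
      span <- .gr0(ch, gs - 1000, gs + glen + 1000, chroms)  # include promoter room
      if (any(IRanges::overlapsAny(span, mask_gr)) ||
          any(IRanges::overlapsAny(span, occupied))) next
      occupied <- c(occupied, .gr0(ch, gs - 2000, gs + glen + 2000, chroms))
      gid <- gid + 1L; placed <- placed + 1L
      id <- sprintf("G%04d", gid)
      strand <- sample(c("+", "-"), 1)
      # transcript-forward layout: 150 bp 5'UTR, CDS exons, 250 bp 3'UTR
      n_ex <- sample(3:5, 1)
      exon_len <- 200
      slots <- seq(200, glen - 500 - exon_len, length.out = n_ex)
      cds_fwd <- cbind(round(slots), round(slots) + exon_len)
      utr5_fwd <- c(0, 150); utr3_fwd <- c(glen - 250, glen)
      tofwd <- function(iv) {
        if (strand == "+") cbind(gs + iv[, 1], gs + iv[, 2])
        else cbind(gs + glen - iv[, 2], gs + glen - iv[, 1])
      }
      cds_ab <- tofwd(cds_fwd)
      u5 <- tofwd(matrix(utr5_fwd, 1)); u3 <- tofwd(matrix(utr3_fwd, 1))
      prom <- if (strand == "+") c(gs - 1000, gs) else c(gs + glen, gs + glen + 1000)
      gtab[[gid]] <- data.frame(gene_id = id, chrom = ch, strand = strand,
                                start = gs, end = gs + glen,
                                promoter_start = max(0, prom[1]),
                                promoter_end = prom[2],
                                stringsAsFactors = FALSE)
      cds[[gid]] <- data.frame(gene_id = id, chrom = ch,
                               start = cds_ab[, 1], end = cds_ab[, 2],
                               stringsAsFactors = FALSE)
      utr[[gid]] <- data.frame(gene_id = id, chrom = ch,
                               start = c(u5[1], u3[1]), end = c(u5[2], u3[2]),
                               side = c("5", "3"), stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, gtab), cds = do.call(rbind, cds),
       utr = do.call(rbind, utr))
}

.draw_lengths <- function(n, lm) {
  comp <- sample(names(lm$weights), n, replace = TRUE, prob = lm$weights)
  len <- numeric(n)
  draw <- function(name, fn) {
    k <- sum(comp == name)
    if (k) len[comp == name] <<- fn(k)
  }
  draw("body", function(k) rlnorm(k, lm$body_meanlog, lm$body_sdlog))
  draw("alu", function(k) rnorm(k, lm$alu_mean, lm$alu_sd))
  draw("line", function(k) rnorm(k, lm$line_mean, lm$line_sd))
  draw("tail", function(k) rlnorm(k, lm$tail_meanlog, lm$tail_sdlog))
  pmin(pmax(round(len), lm$min_len), lm$max_len)
}

.draw_sfs <- function(n, sfs) {
  switch(sfs$kind,
         beta = rbeta(n, sfs$shape1, sfs$shape2),
         uniform = runif(n, sfs$min, sfs$max),
         fixed = rep_len(sfs$af, n),
         stop("unknown sfs kind: ", sfs$kind))
}

#' Simulate a truth SV population
#'
#' Draws SV types, lengths and genomic placements (outside masks; truth loci
#' of one type never overlap each other; loci other than planted pLoF
#' deletions avoid CDS so that planted coding impact is unambiguous), an
#' ancestral allele frequency per locus, Balding-Nichols subpopulation
#' frequencies `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, and Hardy-Weinberg
#' genotypes `~ Binomial(2, p_k)` per sample. Loci left monomorphic by
#' sampling receive one forced heterozygote (the spectrum is conditioned on
#' at least one observed carrier).
#'
#' @param params a [sim_params()] object.
#' @param genome a [simulate_genome()] object.
#' @return list of class `sim_truth`: `svs` (with `p_anc`, per-group truth
#'   frequencies, `af_true`, `plof`, `diff_locus`), `genotypes`
#'   (samples x SVs dosage), `samples` (`sample_id`, `group`), `genome`,
#'   `params`.
#' @export
simulate_population <- function(params, genome) {
  set.seed(params$seed)
  n <- params$n_svs
  type <- sample(.SV_TYPES, n, replace = TRUE, prob = params$type_mix)
  plof <- rep(FALSE, n)
  if (params$n_plof > 0) {
    if (params$n_plof > nrow(genome$genes$genes))
      stop("more planted pLoF loci than genes")
    plof[sample.int(n, params$n_plof)] <- TRUE
    type[plof] <- "DEL"
  }
  diff_locus <- rep(FALSE, n)
  if (params$n_diff > 0) diff_locus[sample(which(!plof), params$n_diff)] <- TRUE
  len <- .draw_lengths(n, params$length_model)
  placed <- .place_svs(type, len, plof, genome)
  p_anc <- .draw_sfs(n, params$sfs)
  p_anc[diff_locus] <- runif(sum(diff_locus), 0.2, 0.8)
  # Balding-Nichols subpopulation frequencies and HWE genotypes
  sp <- params$subpops
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(params$n_samples)),
    group = rep(sp$group, sp$n), stringsAsFactors = FALSE)
  G <- matrix(0L, nrow = params$n_samples, ncol = n,
              dimnames = list(samples$sample_id, NULL))
  p_group <- matrix(NA_real_, nrow = nrow(sp), ncol = n,
                    dimnames = list(sp$group, NULL))
  for (g in seq_len(nrow(sp))) {
    Fg <- sp$F[g]
    pk <- if (Fg == 0) p_anc else
      rbeta(n, p_anc * (1 - Fg) / Fg, (1 - p_anc) * (1 - Fg) / Fg)
    if (any(diff_locus) && sp$group[g] == params$diff_group)
      pk[diff_locus] <- .displaced_freq(p_anc[diff_locus], params$diff_F)
    p_group[g, ] <- pk
    rows <- which(samples$group == sp$group[g])
    G[rows, ] <- matrix(rbinom(length(rows) * n, 2, rep(pk, each = length(rows))),
                        nrow = length(rows))
  }
  mono <- colSums(G) == 0
  if (any(mono)) {
    forced <- sample.int(nrow(G), sum(mono), replace = TRUE)
    G[cbind(forced, which(mono))] <- 1L
  }
  svs <- data.frame(sv_id = sprintf("T%05d", seq_len(n)), sv_type = type,
                    chrom = placed$chrom, start = placed$start,
                    end = placed$start + len, svlen = len,
                    p_anc = p_anc, af_true = colSums(G) / (2 * nrow(G)),
                    plof = plof, diff_locus = diff_locus,
                    stringsAsFactors = FALSE)
  colnames(G) <- svs$sv_id
  structure(list(svs = svs, genotypes = G, samples = samples,
                 genome = genome, p_group = p_group, params = params),
            class = "sim_truth")
}

# Focal-branch frequency for a planted differentiated locus: displace the
# ancestral frequency p by the deterministic delta that sets the true
# Hudson F_ST between the displaced and ancestral frequency to F, i.e.
# delta^2 / (2 p (1 - p) + delta (1 - 2 p)) = F, shifting away from the
# nearer allele-frequency boundary.
.displaced_freq <- function(p, F) {
  up <- p <= 0.5
  s <- ifelse(up, 1 - 2 * p, 2 * p - 1)   # sign-adjusted (1 - 2p)
  delta <- (F * s + sqrt(F^2 * s^2 + 8 * F * p * (1 - p))) / 2
  pmin(pmax(ifelse(up, p + delta, p - delta), 1e-3), 1 - 1e-3)
}

# Place SVs: outside masks, same-type loci disjoint (with a pad), non-pLoF
# loci clear of CDS; planted pLoF deletions straddle a CDS exon.
.place_svs <- function(type, len, plof, genome, pad = 100) {
  n <- length(type)
  chroms <- names(genome$chrom_len)
  chrom <- character(n); start <- numeric(n)
  lv <- chroms
  mask_gr <- .gr0(genome$masks$chrom, genome$masks$start, genome$masks$end, lv)
  cds <- genome$genes$cds
  cds_gr <- .gr0(cds$chrom, cds$start, cds$end, lv)
  forbidden <- c(mask_gr, cds_gr)
  empty_gr <- .gr0(character(), numeric(), numeric(), lv)
  occupied <- stats::setNames(rep(list(empty_gr), length(.SV_TYPES)),
                              .SV_TYPES)
  # planted pLoF deletions first
  if (any(plof)) {
    genes_pick <- sample(unique(cds$gene_id), sum(plof))
    k <- 0L
    for (i in which(plof)) {
      k <- k + 1L
      ex <- cds[cds$gene_id == genes_pick[k], , drop = FALSE][1, ]
      s <- max(0, ex$start - floor(len[i] / 2))
      chrom[i] <- ex$chrom; start[i] <- s
      occupied[["DEL"]] <- c(occupied[["DEL"]],
                             .gr0(ex$chrom, max(0, s - pad), s + len[i] + pad, lv))
    }
  }
  for (tp in .SV_TYPES) {
    idx <- which(type == tp & !plof)
    if (!length(idx)) next
    # longest first, in bands completed before shorter loci are placed:
    # a long locus is only placeable while the genome is sparsely occupied
    band <- cut(len[idx], c(0, 2e3, 2e4, Inf), labels = FALSE)
    for (b in sort(unique(band), decreasing = TRUE)) {
      todo <- idx[band == b]
      todo <- todo[order(-len[todo])]
      guard <- 0L
      while (length(todo) && guard < 500L) {
        guard <- guard + 1L
        ch <- sample(chroms, length(todo), replace = TRUE,
                     prob = genome$chrom_len[chroms])
        s <- floor(runif(length(todo)) * (genome$chrom_len[ch] - len[todo]))
        cand <- .gr0(ch, pmax(0, s - pad), s + len[todo] + pad, lv)
        bad <- IRanges::overlapsAny(cand, forbidden) |
          IRanges::overlapsAny(cand, occupied[[tp]])
        # resolve collisions within the batch: keep the longer of each clash
        self <- GenomicRanges::findOverlaps(cand, cand)
        qh <- S4Vectors::queryHits(self); sh <- S4Vectors::subjectHits(self)
        bad[qh[qh > sh]] <- TRUE
        ok <- !bad
        if (any(ok)) {
          chrom[todo[ok]] <- ch[ok]; start[todo[ok]] <- s[ok]
          occupied[[tp]] <- c(occupied[[tp]], cand[ok])
          todo <- todo[!ok]
        }
      }
      if (length(todo)) stop("could not place all ", tp,
                             " loci; genome too small for n_svs")
    }
  }
  list(chrom = chrom, start = start)
}

#' Emulate one caller over the truth population
#'
#' For each carrier sample and truth SV: emit with the profile's per-type
#' sensitivity, jitter the start by `round(N(0, sd))` and the length by a
#' factor `1 + N(0, cv)`, draw site depth `~ Poisson(depth)` and supporting
#' reads `~ Binomial(depth, 0.5)` for heterozygotes or
#' `Binomial(depth, 1.0)` for homozygotes. False positives are added as
#' `Poisson(fp_rate)` calls per sample at random positions kept clear of
#' same-type truth loci by more than twice the call length, so that no
#' false call can reach 50% reciprocal overlap with a truth SV.
#'
#' @param truth a [simulate_population()] object.
#' @param profile a caller profile (see [default_caller_profiles()]).
#' @param seed integer RNG seed.
#' @return named list `sample_id -> sv_calls`; each table carries a
#'   `truth_id` column (`NA` for false positives).
#' @export
simulate_caller_calls <- function(truth, profile, seed = 1) {
  set.seed(seed)
  G <- truth$genotypes
  svs <- truth$svs
  genome <- truth$genome
  depth_mean <- truth$params$depth
  sens <- profile$sensitivity[svs$sv_type]
  truth_index <- .truth_interval_index(svs)
  out <- list()
  for (i in seq_len(nrow(G))) {
    sid <- rownames(G)[i]
    carrier <- which(G[i, ] >= 1)
    det <- carrier[runif(length(carrier)) < sens[carrier]]
    ndet <- length(det)
    s <- pmax(0, svs$start[det] +
                round(rnorm(ndet, 0, profile$breakpoint_jitter_sd)))
    l <- pmax(1, round(svs$svlen[det] *
                         (1 + rnorm(ndet, 0, profile$length_jitter_cv))))
    dep <- pmax(1, rpois(ndet, depth_mean))
    het <- G[i, det] == 1
    sup <- pmin(dep, pmax(1, rbinom(ndet, dep, ifelse(het, 0.5, 1.0))))
    calls <- sv_calls(sample_id = sid, caller_id = profile$caller_id,
                      sv_type = svs$sv_type[det], chrom = svs$chrom[det],
                      start = s, svlen = l, support_reads = sup,
                      site_depth = dep)
    calls$truth_id <- svs$sv_id[det]
    n_fp <- rpois(1, profile$fp_rate)
    if (n_fp > 0) {
      fp <- .draw_false_calls(n_fp, truth, profile, truth_index)
      fp$sample_id <- sid
      calls <- rbind(calls, fp)
    }
    ord <- order(calls$chrom, calls$start, calls$sv_type)
    calls <- calls[ord, , drop = FALSE]
    rownames(calls) <- NULL
    out[[sid]] <- calls
  }
  out
}

.draw_false_calls <- function(n_fp, truth, profile, truth_index) {
  genome <- truth$genome
  chroms <- names(genome$chrom_len)
  tp <- sample(.SV_TYPES, n_fp, replace = TRUE, prob = truth$params$type_mix)
  len <- .draw_lengths(n_fp, truth$params$length_model)
  chrom <- character(n_fp); start <- numeric(n_fp)
  todo <- seq_len(n_fp); guard <- 0L
  while (length(todo) && guard < 100L) {
    guard <- guard + 1L
    ch <- sample(chroms, length(todo), replace = TRUE,
                 prob = genome$chrom_len[chroms])
    s <- floor(runif(length(todo)) * (genome$chrom_len[ch] - len[todo]))
    # keep clear of same-type truth loci by > 2x the call length
    a <- pmax(0, s - 2 * len[todo]); b <- s + 3 * len[todo]
    bad <- mapply(function(key, a1, b1) .hits_sorted(truth_index[[key]], a1, b1),
                  paste(tp[todo], ch), a, b)
    ok <- !bad
    if (any(ok)) {
      chrom[todo[ok]] <- ch[ok]; start[todo[ok]] <- s[ok]
      todo <- todo[!ok]
    }
  }
  dep <- pmax(1, rpois(n_fp, truth$params$depth))
  sup <- pmin(dep, pmax(1, rbinom(n_fp, dep, 0.5)))
  fp <- sv_calls(sample_id = "tmp", caller_id = profile$caller_id,
                 sv_type = tp, chrom = chrom, start = start, svlen = len,
                 support_reads = sup, site_depth = dep)
  fp$truth_id <- NA_character_
  fp
}

# sorted-interval index: per (type chrom) key, list(starts, cummax_ends)
.truth_interval_index <- function(svs) {
  keys <- paste(svs$sv_type, svs$chrom)
  idx <- lapply(split(seq_len(nrow(svs)), keys), function(i) {
    o <- i[order(svs$start[i])]
    list(starts = svs$start[o], ends = cummax(svs$end[o]))
  })
  idx
}

# does [a, b) overlap any interval in the sorted index entry?
.hits_sorted <- function(entry, a, b) {
  if (is.null(entry)) return(FALSE)
  k <- findInterval(b - 0.5, entry$starts)  # intervals with start < b
  k >= 1 && entry$ends[k] > a
}

#' Emulate a panel of callers
#'
#' Runs [simulate_caller_calls()] for each profile with a seed derived from
#' `seed` and reorganizes the result per sample.
#'
#' @param truth a [simulate_population()] object.
#' @param profiles named list of caller profiles.
#' @param seed integer base seed.
#' @return nested list `sample_id -> caller_id -> sv_calls`.
#' @export
simulate_callsets <- function(truth, profiles = default_caller_profiles(),
                              seed = 1) {
  per_caller <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    per_caller[[p$caller_id]] <-
      simulate_caller_calls(truth, p, seed = seed + 1000L * k)
  }
  samples <- rownames(truth$genotypes)
  out <- lapply(samples, function(sid)
    lapply(per_caller, function(cc) cc[[sid]]))
  names(out) <- samples
  out
}
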