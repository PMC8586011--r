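#' Hudson's F_ST estimator for one site
#'
#' Sample-size-corrected Hudson estimator from allele counts:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(an1-1) - p2(1-p2)/(an2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`. Negative estimates are clamped to 0
#' and the estimate is capped just below 1 so that branch lengths
#' `-ln(1 - F_ST)` stay finite; a zero denominator yields `NA`.
#'
#' @param ac1,an1,ac2,an2 allele counts and totals per population
#'   (vectorized; `an >= 2`).
#' @return F_ST estimates in `[0, 1)`.
#' @export
hudson_fst <- function(ac1, an1, ac2, an2) {
  comp <- hudson_fst_components(ac1, an1, ac2, an2)
  fst <- ifelse(comp$den == 0, NA_real_, comp$num / comp$den)
  pmin(pmax(fst, 0), 1 - 1e-9)
}

#' Hudson numerator and denominator
#'
#' Exposed separately so that multi-site (ratio-of-sums) estimates can be
#' formed, the standard way to combine Hudson F_ST across loci.
#'
#' @inheritParams hudson_fst
#' @return list with vectors `num` and `den`.
#' @export
hudson_fst_components <- function(ac1, an1, ac2, an2) {
  if (any(an1 < 2) || any(an2 < 2)) stop("allele totals must be >= 2")
  p1 <- ac1 / an1; p2 <- ac2 / an2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Multi-site Hudson F_ST (ratio of sums)
#'
#' Combines loci the recommended way — summing Hudson numerators and
#' denominators before taking the ratio, which is nearly unbiased where the
#' mean of per-site ratios is not. The standard error comes from splitting
#' the loci into blocks and taking the dispersion of per-block ratios.
#'
#' @inheritParams hudson_fst
#' @param n_blocks number of blocks for the SE (default 100).
#' @return list with `fst`, `se` and `n_sites`.
#' @export
hudson_fst_multi <- function(ac1, an1, ac2, an2, n_blocks = 100) {
  comp <- hudson_fst_components(ac1, an1, ac2, an2)
  ok <- !is.na(comp$num) & !is.na(comp$den) & comp$den > 0
  num <- comp$num[ok]; den <- comp$den[ok]
  blk <- rep_len(seq_len(n_blocks), length(num))
  br <- tapply(num, blk, sum) / tapply(den, blk, sum)
  list(fst = sum(num) / sum(den),
       se = stats::sd(br) / sqrt(length(br)), n_sites = length(num))
}

#' Population branch statistic
#'
#' `PBS_A = (-ln(1 - F_AB) - ln(1 - F_AC) + ln(1 - F_BC)) / 2`, clamped at
#' 0: the branch length specific to population A, from pairwise F_ST against
#' the sister population B and outgroup C.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise F_ST values in `[0, 1)`
#'   (vectorized).
#' @return PBS values `>= 0`.
#' @export
#' @examples
#' pbs(0.5, 0.5, 0)    # log(2)
#' pbs(0.1, 0.1, 0.1)  # -log(0.9)/2
pbs <- function(fst_ab, fst_ac, fst_bc) {
  stopifnot(all(fst_ab >= 0 & fst_ab < 1, na.rm = TRUE),
            all(fst_ac >= 0 & fst_ac < 1, na.rm = TRUE),
            all(fst_bc >= 0 & fst_bc < 1, na.rm = TRUE))
  pmax((-log(1 - fst_ab) - log(1 - fst_ac) + log(1 - fst_bc)) / 2, 0)
}

#' PBS selection scan over a population SV set
#'
#' Filters to pooled minor allele frequency above `maf_min`, computes the
#' three pairwise Hudson F_ST values and the focal-branch PBS per SV, sets
#' the threshold at the empirical `rank` quantile of the focal scores
#' (NA scores excluded), and chains above-threshold SVs within `merge_bp`
#' of each other on one chromosome into independent signals.
#'
#' @param popset an `sv_popset` (or list with `svs` and a samples-x-SVs
#'   dosage matrix `genotypes`).
#' @param focal,sister,outgroup character vectors of sample ids (each group
#'   `>= 2` samples).
#' @param maf_min pooled-MAF filter (default 0.01, strict `>`).
#' @param rank quantile defining the outlier threshold (default 0.999).
#' @param merge_bp chaining distance for signals (default 1 Mb).
#' @return list with `records` (per-SV data frame: allele frequencies,
#'   pairwise F_ST, `pbs`, `above_threshold`, `signal_id`), `threshold`,
#'   and `signals` (one row per chained signal).
#' @export
pbs_scan <- function(popset, focal, sister, outgroup, maf_min = 0.01,
                     rank = 0.999, merge_bp = 1e6) {
  G <- popset$genotypes
  groups <- list(focal = focal, sister = sister, outgroup = outgroup)
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2) stop(g, " group has fewer than 2 samples")
    if (!all(groups[[g]] %in% rownames(G))) stop("unknown samples in ", g, " group")
  }
  ac <- lapply(groups, function(s) colSums(G[s, , drop = FALSE], na.rm = TRUE))
  an <- lapply(groups, function(s) 2 * colSums(!is.na(G[s, , drop = FALSE])))
  ac_tot <- Reduce(`+`, ac); an_tot <- Reduce(`+`, an)
  af_pool <- ac_tot / an_tot
  maf_pool <- pmin(af_pool, 1 - af_pool)
  keep <- !is.na(maf_pool) & maf_pool > maf_min
  svs <- popset$svs[keep, , drop = FALSE]
  ac <- lapply(ac, `[`, keep); an <- lapply(an, `[`, keep)
  fst_ab <- hudson_fst(ac$focal, an$focal, ac$sister, an$sister)
  fst_ac <- hudson_fst(ac$focal, an$focal, ac$outgroup, an$outgroup)
  fst_bc <- hudson_fst(ac$sister, an$sister, ac$outgroup, an$outgroup)
  score <- pbs(fst_ab, fst_ac, fst_bc)
  threshold <- stats::quantile(score, rank, na.rm = TRUE, names = FALSE)
  above <- !is.na(score) & score > threshold
  records <- data.frame(
    sv_id = svs$sv_id, chrom = svs$chrom, start = svs$start,
    p_focal = ac$focal / an$focal, p_sister = ac$sister / an$sister,
    p_outgroup = ac$outgroup / an$outgroup,
    fst_ab = fst_ab, fst_ac = fst_ac, fst_bc = fst_bc,
    pbs = score, above_threshold = above, signal_id = NA_integer_,
    stringsAsFactors = FALSE)
  records <- .chain_signals(records, merge_bp)
  above <- records$above_threshold
  signals <- NULL
  if (any(above)) {
    asv <- records[above, , drop = FALSE]
    signals <- do.call(rbind, lapply(split(asv, asv$signal_id), function(d)
      data.frame(signal_id = d$signal_id[1], chrom = d$chrom[1],
                 start = min(d$start), end = max(d$start),
                 n_svs = nrow(d), max_pbs = max(d$pbs),
                 stringsAsFactors = FALSE)))
    rownames(signals) <- NULL
  }
  list(records = records, threshold = threshold, signals = signals)
}

# assign signal ids: above-threshold records within merge_bp of each other
# on one chromosome share a signal
.chain_signals <- function(records, merge_bp = 1e6) {
  records$signal_id <- NA_integer_
  above <- records$above_threshold
  sig <- 0L
  for (ch in unique(records$chrom[above])) {
    idx <- which(above & records$chrom == ch)
    idx <- idx[order(records$start[idx])]
    pos <- records$start[idx]
    ids <- cumsum(c(TRUE, diff(pos) > merge_bp)) + sig
    records$signal_id[idx] <- ids
    sig <- max(ids)
  }
  records
}

#' Identity-by-state kinship matrix
#'
#' `IBS(i, j)` = mean over sites of `(2 - |g_i - g_j|) / 2` on 0/1/2 dosage
#' genotypes; pairwise-complete over missing sites; diagonal 1.
#'
#' @param genotypes samples x SVs dosage matrix.
#' @return symmetric samples x samples matrix in `[0, 1]`.
#' @export
ibs_matrix <- function(genotypes) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  M <- diag(1, n)
  rownames(M) <- colnames(M) <- rownames(G)
  if (n < 2) return(M)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- abs(G[i, ] - G[j, ])
      M[i, j] <- M[j, i] <- mean((2 - d) / 2, na.rm = TRUE)
    }
  }
  M
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / n_tests`, reported to two significant figures
#' (0.05 / 29,510 tests gives 1.7e-6).
#'
#' @param n_tests number of association tests (`>= 1`).
#' @param alpha family-wise error rate (default 0.05).
#' @return significance threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (any(n_tests < 1)) stop("n_tests must be >= 1")
  signif(alpha / n_tests, 2)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts (the standard SNP-HWE
#' enumeration over heterozygote counts given the allele counts), returning
#' the sum of probabilities of configurations no more likely than the
#' observed one. Used to check simulated genotype matrices.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized conditional probabilities via log factorials
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-12)])
}
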