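#' Genotype from variant allele balance
#'
#' VAB = supporting reads / site depth. Genotype is `0/0` for VAB <= 0.2,
#' `0/1` for 0.2 < VAB <= 0.8, `1/1` for VAB > 0.8, and `./.` when the site
#' depth is zero or unknown.
#'
#' @param support_reads,site_depth integer vectors (recycled).
#' @return character vector of genotypes.
#' @export
#' @examples
#' genotype_from_vab(c(2, 5, 9), 10)  # "0/0" "0/1" "1/1"
genotype_from_vab <- function(support_reads, site_depth) {
  n <- max(length(support_reads), length(site_depth))
  s <- rep_len(as.numeric(support_reads), n)
  d <- rep_len(as.numeric(site_depth), n)
  known <- !is.na(d) & d > 0
  if (any(s[known] > d[known])) stop("support_reads exceeds site_depth")
  vab <- ifelse(known, s / d, NA_real_)
  gt <- rep("./.", n)
  gt[known & vab <= 0.2] <- "0/0"
  gt[known & vab > 0.2 & vab <= 0.8] <- "0/1"
  gt[known & vab > 0.8] <- "1/1"
  gt
}

.gt_dosage <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)

#' Classify allele-frequency category
#'
#' Four categories: singleton (allele count = 1), rare (allele count > 1 and
#' AF <= 0.01), low (0.01 < AF <= 0.05), common (AF > 0.05).
#'
#' @param AC alternate allele counts (> 0).
#' @param AN total called alleles.
#' @return character vector in `{singleton, rare, low, common}`.
#' @export
#' @examples
#' classify_af(c(1, 8, 9, 41), 810)
classify_af <- function(AC, AN) {
  n <- max(length(AC), length(AN))
  AC <- rep_len(AC, n); AN <- rep_len(AN, n)
  if (any(AC <= 0)) stop("AC must be positive (monomorphic reference site)")
  if (any(AC > AN)) stop("AC exceeds AN")
  af <- AC / AN
  ifelse(AC == 1, "singleton",
         ifelse(af <= 0.01, "rare", ifelse(af <= 0.05, "low", "common")))
}

#' Merge filtered per-sample callsets into a nonredundant population set
#'
#' Cross-sample CAST clustering per SV type and chromosome with the same
#' 50% mutual-overlap affinity as the within-sample merge. Each cluster
#' becomes one population SV whose representative is the member whose
#' `(start, svlen)` pair occurs in the most samples (ties: higher
#' `support_reads`, then smaller start). Samples contributing a member are
#' genotyped from that member's variant allele balance; samples without a
#' member are genotyped `0/0`. `./.` is reserved for members with unknown
#' depth. Clusters whose genotypes carry no alternate allele (all `0/0` or
#' missing) are retained with `category = NA`.
#'
#' @param per_sample named list `sample_id -> sv_calls` of merged, filtered
#'   calls.
#' @param threshold CAST affinity threshold.
#' @return object of class `sv_popset`: list with
#'   \describe{
#'     \item{svs}{data frame: `sv_id`, `sv_type`, `chrom`, `start`, `end`,
#'       `svlen`, `n_detected`, `AC`, `AN`, `AF`, `MAF`, `category`.}
#'     \item{genotypes}{integer dosage matrix samples x SVs (0/1/2, `NA`
#'       for `./.`).}
#'     \item{samples}{character vector of sample ids.}
#'   }
#' @export
merge_population <- function(per_sample, threshold = 0.5) {
  samples <- names(per_sample)
  if (is.null(samples) || any(samples == ""))
    stop("per_sample must be a named list of sample callsets")
  pooled <- .bind_calls(per_sample)
  if (nrow(pooled) == 0) stop("no calls to merge")
  clusters <- .cluster_pooled(pooled, threshold)
  n_multi <- 0L
  recs <- vector("list", length(clusters))
  G <- matrix(0L, nrow = length(samples), ncol = length(clusters),
              dimnames = list(samples, NULL))
  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    # one member per sample: keep the higher-support member
    if (anyDuplicated(cl$sample_id)) {
      n_multi <- n_multi + sum(duplicated(cl$sample_id))
      ord <- order(cl$sample_id, -cl$support_reads, cl$start)
      cl <- cl[ord, , drop = FALSE]
      cl <- cl[!duplicated(cl$sample_id), , drop = FALSE]
    }
    key <- paste(cl$start, cl$svlen)
    tab <- table(key)
    top <- names(tab)[tab == max(tab)]
    cand <- which(key %in% top)
    cand <- cand[order(-cl$support_reads[cand], cl$start[cand])][1]
    rep <- cl[cand, , drop = FALSE]
    gt <- genotype_from_vab(cl$support_reads, cl$site_depth)
    dos <- unname(.gt_dosage[gt])
    G[match(cl$sample_id, samples), j] <- as.integer(dos)
    recs[[j]] <- data.frame(sv_type = rep$sv_type, chrom = rep$chrom,
                            start = rep$start, end = rep$end,
                            svlen = rep$svlen, n_detected = nrow(cl),
                            stringsAsFactors = FALSE)
  }
  if (n_multi > 0)
    warning(n_multi, " sample(s) contributed multiple members to a cluster; ",
            "kept the higher-support member")
  svs <- do.call(rbind, recs)
  ord <- order(svs$chrom, svs$start, svs$sv_type, svs$svlen)
  svs <- svs[ord, , drop = FALSE]
  G <- G[, ord, drop = FALSE]
  svs$sv_id <- sprintf("SV%06d", seq_len(nrow(svs)))
  colnames(G) <- svs$sv_id
  rownames(svs) <- NULL
  svs$AC <- as.integer(colSums(G, na.rm = TRUE))
  svs$AN <- as.integer(2L * colSums(!is.na(G)))
  svs$AF <- ifelse(svs$AN > 0, svs$AC / svs$AN, NA_real_)
  svs$MAF <- pmin(svs$AF, 1 - svs$AF)
  svs$category <- NA_character_
  poly <- svs$AC > 0
  svs$category[poly] <- classify_af(svs$AC[poly], svs$AN[poly])
  svs <- svs[, c("sv_id", "sv_type", "chrom", "start", "end", "svlen",
                 "n_detected", "AC", "AN", "AF", "MAF", "category")]
  structure(list(svs = svs, genotypes = G, samples = samples),
            class = "sv_popset")
}

#' @param x an `sv_popset` object.
#' @param ... ignored.
#' @rdname merge_population
#' @method print sv_popset
#' @export
print.sv_popset <- function(x, ...) {
  cat("Nonredundant population SV set:", nrow(x$svs), "SVs,",
      length(x$samples), "samples\n")
  cat("Types:\n"); print(table(x$svs$sv_type))
  cat("AF categories:\n"); print(table(x$svs$category, useNA = "ifany"))
  invisible(x)
}

#' Category discovery curves under population subsampling
#'
#' Re-merges random subsets of samples at increasing subset sizes and counts
#' the nonredundant SVs per allele-frequency category, averaging over
#' replicate draws.
#'
#' @param per_sample named list `sample_id -> sv_calls` (merged, filtered).
#' @param sizes integer vector of subset sizes.
#' @param reps replicate draws per size (default 4).
#' @param seed integer RNG seed.
#' @param threshold CAST affinity threshold.
#' @return data frame `size` x `category` -> `mean_count`, plus
#'   `total` = mean number of polymorphic nonredundant SVs.
#' @export
subsample_curve <- function(per_sample, sizes, reps = 4, seed = 1,
                            threshold = 0.5) {
  if (any(sizes > length(per_sample))) stop("size exceeds available samples")
  set.seed(seed)
  cats <- c("singleton", "rare", "low", "common")
  out <- list()
  for (sz in sizes) {
    counts <- matrix(0, nrow = reps, ncol = length(cats) + 1,
                     dimnames = list(NULL, c(cats, "total")))
    for (r in seq_len(reps)) {
      sub <- sample(names(per_sample), sz)
      pop <- merge_population(per_sample[sub], threshold)
      tab <- table(factor(pop$svs$category, levels = cats))
      counts[r, cats] <- as.numeric(tab)
      counts[r, "total"] <- sum(tab)
    }
    out[[length(out) + 1]] <- data.frame(size = sz,
                                         category = c(cats, "total"),
                                         mean_count = colMeans(counts),
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
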