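#' Support-read filter
#'
#' Keeps calls supported by at least `min_reads` reads. In depth-scaled mode
#' (`depth_ratio` set) the threshold is instead
#' `round(depth_ratio * mean_depth)`: a ratio of 0.2 equals 3 supporting
#' reads at 15-fold coverage, the production operating point.
#'
#' @param calls `sv_calls` data frame (merged representatives).
#' @param min_reads fixed minimum supporting reads (default 3).
#' @param depth_ratio optional fraction of mean depth replacing `min_reads`.
#' @param mean_depth mean sample depth for depth-scaled mode; defaults to
#'   the mean of the calls' known `site_depth`.
#' @return filtered `sv_calls`.
#' @export
filter_support <- function(calls, min_reads = 3, depth_ratio = NULL,
                           mean_depth = NULL) {
  if (nrow(calls) == 0) return(calls)
  thr <- min_reads
  if (!is.null(depth_ratio)) {
    if (is.null(mean_depth)) mean_depth <- mean(calls$site_depth, na.rm = TRUE)
    thr <- round(depth_ratio * mean_depth)
  }
  calls[!is.na(calls$support_reads) & calls$support_reads >= thr, , drop = FALSE]
}

#' Length filter
#'
#' Drops DEL/INS longer than `max_del_ins` (2 Mb), DUP/INV longer than
#' `max_dup_inv` (5 Mb), and any SV shorter than `min_len` (50 bp).
#'
#' @param calls `sv_calls` data frame.
#' @param max_del_ins,max_dup_inv,min_len length bounds in bp.
#' @return filtered `sv_calls`.
#' @export
filter_length <- function(calls, max_del_ins = 2e6, max_dup_inv = 5e6,
                          min_len = 50) {
  if (nrow(calls) == 0) return(calls)
  too_long <- ifelse(calls$sv_type %in% c("DEL", "INS"),
                     calls$svlen > max_del_ins, calls$svlen > max_dup_inv)
  calls[!too_long & calls$svlen >= min_len, , drop = FALSE]
}

#' Region mask filter
#'
#' Drops any call whose interval (INS: the synthetic interval) intersects a
#' mask interval by at least 1 bp — the BEDTools-default intersection
#' semantics. Masks typically carry centromeres, assembly gaps ("N" runs)
#' and high-depth (>= 500x) regions.
#'
#' @param calls `sv_calls` data frame.
#' @param masks region mask data frame with columns `label`, `chrom`,
#'   `start`, `end` (0-based half-open), e.g. from [read_region_bed()].
#' @return filtered `sv_calls`.
#' @export
filter_regions <- function(calls, masks) {
  if (nrow(calls) == 0 || is.null(masks) || nrow(masks) == 0) return(calls)
  cg <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start + 1, calls$end))
  mg <- GenomicRanges::GRanges(masks$chrom,
                               IRanges::IRanges(masks$start + 1, masks$end))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(cg, mg)))
  if (length(hit)) calls[-hit, , drop = FALSE] else calls
}

#' Three-step filtering cascade with removal accounting
#'
#' Applies the support, length and region filters in order and reports the
#' per-step removal counts.
#'
#' @inheritParams filter_support
#' @inheritParams filter_length
#' @inheritParams filter_regions
#' @return list with `calls` (the filtered table) and `report`: a list with
#'   `n_input`, `n_after_support`, `n_after_length`, `n_after_region` and
#'   `removed_per_step`.
#' @export
filter_pipeline <- function(calls, masks = NULL, min_reads = 3,
                            depth_ratio = NULL, mean_depth = NULL,
                            max_del_ins = 2e6, max_dup_inv = 5e6,
                            min_len = 50) {
  n0 <- nrow(calls)
  c1 <- filter_support(calls, min_reads, depth_ratio, mean_depth)
  c2 <- filter_length(c1, max_del_ins, max_dup_inv, min_len)
  c3 <- filter_regions(c2, masks)
  report <- list(
    n_input = n0,
    n_after_support = nrow(c1),
    n_after_length = nrow(c2),
    n_after_region = nrow(c3),
    removed_per_step = c(support = n0 - nrow(c1),
                         length = nrow(c1) - nrow(c2),
                         region = nrow(c2) - nrow(c3)))
  list(calls = c3, report = report)
}
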