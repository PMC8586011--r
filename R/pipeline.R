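#' One sample end to end: ensemble merge plus filtering cascade
#'
#' @param callsets named list `caller -> sv_calls` for one sample.
#' @param masks region masks (or NULL).
#' @param min_callers consensus requirement (default 2).
#' @param min_reads support filter threshold (default 3).
#' @param ... further arguments to [filter_pipeline()].
#' @return list with `calls` (merged, filtered `sv_calls`) and `report`.
#' @export
run_sample_pipeline <- function(callsets, masks = NULL, min_callers = 2,
                                min_reads = 3, ...) {
  merged <- merge_within_sample(callsets, min_callers = min_callers)
  filter_pipeline(merged, masks = masks, min_reads = min_reads, ...)
}

#' Full population pipeline over simulated or loaded callsets
#'
#' Runs the per-sample ensemble merge and filtering for every sample, then
#' the cross-sample nonredundant merge with variant-allele-balance
#' genotyping and allele-frequency classing.
#'
#' @param callsets_by_sample nested list `sample -> caller -> sv_calls`.
#' @param masks region masks (or NULL).
#' @inheritParams run_sample_pipeline
#' @return list with `popset` (`sv_popset`), `per_sample` (filtered calls)
#'   and `reports` (per-sample filter reports).
#' @export
run_population_pipeline <- function(callsets_by_sample, masks = NULL,
                                    min_callers = 2, min_reads = 3, ...) {
  per_sample <- list(); reports <- list()
  for (sid in names(callsets_by_sample)) {
    res <- run_sample_pipeline(callsets_by_sample[[sid]], masks = masks,
                               min_callers = min_callers,
                               min_reads = min_reads, ...)
    per_sample[[sid]] <- res$calls
    reports[[sid]] <- res$report
  }
  popset <- merge_population(per_sample)
  list(popset = popset, per_sample = per_sample, reports = reports)
}
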