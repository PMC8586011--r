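#' Normalize an external SV reference table
#'
#' Maps external types onto the canonical four: CNV copy gain -> DUP, copy
#' loss -> DEL, mobile element insertions (MEI/ALU/LINE1/SVA) -> INS.
#' INS records without a usable length are excluded (both length and
#' position enter the reciprocal-overlap test). INS end coordinates are
#' rebuilt as `start + svlen` (the synthetic-interval convention).
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `type`, and optionally `svlen`.
#' @return `sv_calls` data frame with `caller_id = "other"`.
#' @export
normalize_external_sv <- function(df) {
  type <- toupper(df$type)
  type[type %in% c("CNV:GAIN", "GAIN", "COPY_GAIN")] <- "DUP"
  type[type %in% c("CNV:LOSS", "LOSS", "COPY_LOSS")] <- "DEL"
  type[type %in% c("MEI", "ALU", "LINE1", "L1", "SVA", "INS:ME")] <- "INS"
  keep <- type %in% .SV_TYPES
  df <- df[keep, , drop = FALSE]; type <- type[keep]
  svlen <- if ("svlen" %in% names(df)) df$svlen else rep(NA_real_, nrow(df))
  # INS records need an explicit length; the reference footprint is a point
  drop_ins <- type == "INS" & (is.na(svlen) | svlen < 1)
  svlen <- ifelse(is.na(svlen), df$end - df$start, svlen)
  df <- df[!drop_ins, , drop = FALSE]
  type <- type[!drop_ins]; svlen <- svlen[!drop_ins]
  sv_calls(sample_id = "ref", caller_id = "other", sv_type = type,
           chrom = df$chrom, start = df$start, svlen = svlen,
           support_reads = 0, site_depth = NA_real_)
}

# matched flag for each row of `query` against `ref` (same type, same
# chromosome, reciprocal overlap > frac, or >= when strict = FALSE)
.match_flags <- function(query, ref, frac = 0.5, strict = TRUE) {
  matched <- rep(FALSE, nrow(query))
  if (nrow(query) == 0 || nrow(ref) == 0) return(matched)
  qg <- .sv_gr(query); rg <- .sv_gr(ref)
  ov <- GenomicRanges::findOverlaps(qg, rg)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  same <- query$sv_type[qh] == ref$sv_type[sh] &
    query$chrom[qh] == ref$chrom[sh]
  qh <- qh[same]; sh <- sh[same]
  if (!length(qh)) return(matched)
  ovlen <- pmin(query$end[qh], ref$end[sh]) - pmax(query$start[qh], ref$start[sh])
  ro <- ovlen / pmax(query$end[qh] - query$start[qh], ref$end[sh] - ref$start[sh])
  hit <- if (strict) ro > frac else ro >= frac
  matched[unique(qh[hit])] <- TRUE
  matched
}

#' Match a query SV set against an external reference set
#'
#' An SV is matched when some reference record of the same type has
#' reciprocal overlap larger than `frac` (strict `>`, per the published
#' comparison convention; the within-sample merge uses `>=`). Novel SVs are
#' those unmatched against the union of all supplied references.
#'
#' @param query SV table (popset `svs` or `sv_calls`).
#' @param refs a single normalized reference table or a list of them.
#' @param frac reciprocal-overlap threshold (default 0.5).
#' @param strict use strict `>` (default TRUE).
#' @return `query` with logical columns `matched` and `novel` plus an
#'   attribute `counts` = c(matched, novel).
#' @export
match_reciprocal <- function(query, refs, frac = 0.5, strict = TRUE) {
  if (is.data.frame(refs)) refs <- list(refs)
  matched <- rep(FALSE, nrow(query))
  for (ref in refs) matched <- matched | .match_flags(query, ref, frac, strict)
  query$matched <- matched
  query$novel <- !matched
  attr(query, "counts") <- c(matched = sum(matched), novel = sum(!matched))
  query
}

#' Recall of a reference set by a query set
#'
#' Fraction of reference records matched by the query under the same
#' type-aware reciprocal-overlap rule.
#'
#' @param ref normalized reference SV table (non-empty).
#' @param query SV table.
#' @inheritParams match_reciprocal
#' @return fraction in `[0, 1]`.
#' @export
recall_rate <- function(ref, query, frac = 0.5, strict = TRUE) {
  if (nrow(ref) == 0) stop("recall undefined for an empty reference set")
  mean(.match_flags(ref, query, frac, strict))
}

#' False discovery rate against a truth set
#'
#' FDR = (calls unmatched in the truth set) / (all calls), overall and per
#' SV type, with the percentage reported to one decimal.
#'
#' @param calls SV table to evaluate (non-empty).
#' @param truth truth SV table.
#' @inheritParams match_reciprocal
#' @return list with `n_calls`, `n_false`, `fdr` (fraction),
#'   `fdr_percent` (one decimal), and `per_type` (data frame).
#' @export
evaluate_fdr <- function(calls, truth, frac = 0.5, strict = TRUE) {
  if (nrow(calls) == 0) stop("FDR undefined for an empty callset")
  matched <- .match_flags(calls, truth, frac, strict)
  per_type <- do.call(rbind, lapply(intersect(.SV_TYPES, unique(calls$sv_type)),
    function(tp) {
      sel <- calls$sv_type == tp
      data.frame(sv_type = tp, n_calls = sum(sel),
                 n_false = sum(!matched[sel]),
                 fdr_percent = fdr_percent(sum(!matched[sel]), sum(sel)),
                 stringsAsFactors = FALSE)
    }))
  list(n_calls = nrow(calls), n_false = sum(!matched),
       fdr = sum(!matched) / nrow(calls),
       fdr_percent = fdr_percent(sum(!matched), nrow(calls)),
       per_type = per_type)
}

#' FDR percentage from counts
#'
#' @param n_false number of false-positive calls.
#' @param n_total total number of calls.
#' @return percentage rounded to one decimal, e.g.
#'   `fdr_percent(608, 18737)` is `3.2`.
#' @export
fdr_percent <- function(n_false, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  round(100 * n_false / n_total, 1)
}
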