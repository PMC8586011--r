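#' svpop: population-scale structural variant post-processing
#'
#' Multi-caller SV ensemble merging (CAST clustering at 50% mutual
#' reciprocal overlap), quality filtering, variant-allele-balance
#' genotyping, population-level nonredundant merging with allele-frequency
#' classing, annotation, external comparison/FDR, density profiles,
#' population differentiation statistics, and a callset simulator.
#'
#' @keywords internal
#' @importFrom stats rbinom rpois rnorm runif rbeta rlnorm quantile
#'   fisher.test p.adjust setNames aggregate dbinom
#' @importFrom utils head read.table write.table
"_PACKAGE"

# Caller identifiers in representative-priority order (best first).
.CALLERS <- c("sniffles", "nanovar", "nanosv", "truth", "other")

.SV_TYPES <- c("DEL", "INS", "DUP", "INV")

.SV_COLS <- c("sample_id", "caller_id", "sv_type", "chrom", "start", "end",
              "svlen", "support_reads", "site_depth")

#' Construct a table of SV calls
#'
#' The internal data model is a plain data frame with one row per call.
#' Coordinates are 0-based half-open. For DEL/DUP/INV, `end - start == svlen`
#' (the reference footprint); for INS the same identity holds because the
#' interval is the synthetic one `[start, start + svlen)` used throughout for
#' overlap computations (the reference footprint of an insertion is the
#' point at `start`).
#'
#' @param sample_id,caller_id,sv_type,chrom character vectors (recycled).
#'   `caller_id` one of `"sniffles"`, `"nanovar"`, `"nanosv"`, `"truth"`,
#'   `"other"`; `sv_type` one of `"DEL"`, `"INS"`, `"DUP"`, `"INV"`.
#' @param start 0-based inclusive start positions.
#' @param svlen SV lengths in bp, `>= 1`.
#' @param support_reads supporting read counts, `>= 0`.
#' @param site_depth total read depth at the site; `NA` when unknown.
#' @return A validated `data.frame` of class `sv_calls`.
#' @export
#' @examples
#' sv_calls(sample_id = "s1", caller_id = "sniffles", sv_type = "DEL",
#'          chrom = "chr1", start = 1000, svlen = 300,
#'          support_reads = 10, site_depth = 15)
sv_calls <- function(sample_id = character(), caller_id = character(),
                     sv_type = character(), chrom = character(),
                     start = numeric(), svlen = numeric(),
                     support_reads = numeric(), site_depth = NA_real_) {
  n <- max(length(sample_id), length(caller_id), length(sv_type),
           length(chrom), length(start), length(svlen),
           length(support_reads))
  if (length(start) == 0) n <- 0
  r <- function(x, as) rep_len(as(x), n)
  df <- data.frame(sample_id = r(sample_id, as.character),
                   caller_id = r(caller_id, as.character),
                   sv_type = r(sv_type, as.character),
                   chrom = r(chrom, as.character),
                   start = r(start, as.numeric),
                   end = r(start, as.numeric) + r(svlen, as.numeric),
                   svlen = r(svlen, as.numeric),
                   support_reads = r(support_reads, as.numeric),
                   site_depth = r(site_depth, as.numeric),
                   stringsAsFactors = FALSE)
  validate_sv_calls(df)
}

#' Validate an SV call table
#'
#' Checks column presence, coordinate and length invariants, and the
#' `support_reads <= site_depth` constraint where depth is known.
#'
#' @param df a data frame with the `sv_calls` columns.
#' @return `df`, with class `sv_calls` prepended, invisibly unchanged.
#' @export
validate_sv_calls <- function(df) {
  miss <- setdiff(.SV_COLS, names(df))
  if (length(miss)) stop("missing sv_calls columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (!all(df$caller_id %in% .CALLERS))
      stop("unknown caller_id: ",
           paste(unique(setdiff(df$caller_id, .CALLERS)), collapse = ", "))
    if (!all(df$sv_type %in% .SV_TYPES))
      stop("unknown sv_type: ",
           paste(unique(setdiff(df$sv_type, .SV_TYPES)), collapse = ", "))
    if (any(df$start < 0)) stop("negative start coordinate")
    if (any(df$svlen < 1)) stop("svlen must be >= 1")
    if (any(df$end - df$start != df$svlen))
      stop("end - start must equal svlen (INS uses the synthetic interval)")
    if (any(df$support_reads < 0, na.rm = TRUE)) stop("negative support_reads")
    known <- !is.na(df$site_depth)
    if (any(df$support_reads[known] > df$site_depth[known]))
      stop("support_reads exceeds site_depth")
  }
  class(df) <- unique(c("sv_calls", class(df)))
  df
}

#' Empty SV call table
#' @return zero-row `sv_calls` data frame.
#' @export
empty_sv_calls <- function() sv_calls()

# rbind that tolerates extra columns by keeping only the common model
.bind_calls <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (!length(lst)) return(empty_sv_calls())
  out <- do.call(rbind, lapply(lst, function(x) x[, .SV_COLS, drop = FALSE]))
  rownames(out) <- NULL
  validate_sv_calls(out)
}

# Deterministic preference order used for every tie-break:
# smaller start, then longer svlen, then caller priority. Returns a rank
# vector (1 = most preferred).
.pref_rank <- function(df) {
  ord <- order(df$start, -df$svlen, match(df$caller_id, .CALLERS))
  r <- integer(nrow(df))
  r[ord] <- seq_len(nrow(df))
  r
}
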