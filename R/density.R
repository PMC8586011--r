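#' Meta-chromosome position
#'
#' Maps a position onto the 0-2 arm scale: 0-1 spans the p arm from
#' telomere to centromere, 1-2 the q arm from centromere to telomere.
#' Positions inside the centromere yield `NA` (centromeric SVs are filtered
#' upstream).
#'
#' @param chrom,pos chromosome names and 0-based positions (vectorized).
#' @param arms data frame with columns `chrom`, `p_start`, `cen_start`,
#'   `cen_end`, `q_end` (0-based).
#' @return numeric vector in `[0, 2]`.
#' @export
meta_position <- function(chrom, pos, arms) {
  i <- match(chrom, arms$chrom)
  if (anyNA(i)) stop("arm definition missing for: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  p_start <- arms$p_start[i]; cs <- arms$cen_start[i]
  ce <- arms$cen_end[i]; q_end <- arms$q_end[i]
  out <- rep(NA_real_, length(pos))
  onp <- pos >= p_start & pos < cs
  onq <- pos >= ce & pos <= q_end
  out[onp] <- (pos[onp] - p_start[onp]) / (cs[onp] - p_start[onp])
  out[onq] <- 1 + (pos[onq] - ce[onq]) / (q_end[onq] - ce[onq])
  out
}

#' Meta-chromosome SV density profile
#'
#' Slides a window (default 100 kb, 50 kb step) along every chromosome arm,
#' counts SV midpoints per window and per type, places each window at the
#' normalized 0-2 position of its center, and aggregates across chromosomes
#' by averaging window counts within fixed bins of the normalized scale.
#'
#' @param svs SV table (`chrom`, `start`, `end`, `sv_type`).
#' @param arms arm table (see [meta_position()]).
#' @param window,step window width and slide step in bp.
#' @param bin_width bin width on the normalized 0-2 scale for aggregation.
#' @return list with `windows` (per-chromosome window counts with
#'   `norm_center`) and `profile` (per-bin mean window count, per type and
#'   total).
#' @export
density_profile <- function(svs, arms, window = 1e5, step = 5e4,
                            bin_width = 0.02) {
  mids <- floor((svs$start + svs$end) / 2)
  wins <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") a$p_start else a$cen_end
      hi <- if (arm == "p") a$cen_start else a$q_end
      if (hi - lo < 1) next
      starts <- seq(lo, hi - 1, by = step)
      ends <- pmin(starts + window, hi)
      centers <- (starts + ends) / 2
      counts <- matrix(0L, nrow = length(starts), ncol = length(.SV_TYPES),
                       dimnames = list(NULL, .SV_TYPES))
      sel <- svs$chrom == a$chrom & mids >= lo & mids < hi
      if (any(sel)) {
        m <- mids[sel]; tp <- svs$sv_type[sel]
        for (k in seq_along(starts)) {
          inw <- m >= starts[k] & m < ends[k]
          if (any(inw)) {
            tab <- table(factor(tp[inw], levels = .SV_TYPES))
            counts[k, ] <- as.integer(tab)
          }
        }
      }
      wins[[length(wins) + 1]] <- data.frame(
        chrom = a$chrom, arm = arm, win_start = starts, win_end = ends,
        norm_center = meta_position(rep(a$chrom, length(centers)),
                                    pmin(centers, a$q_end), arms),
        counts, total = rowSums(counts), stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, wins)
  breaks <- seq(0, 2, by = bin_width)
  bin <- cut(windows$norm_center, breaks, include.lowest = TRUE)
  prof <- aggregate(windows[, c(.SV_TYPES, "total")], list(bin = bin), mean)
  prof$bin_mid <- breaks[as.integer(prof$bin)] + bin_width / 2
  list(windows = windows, profile = prof)
}
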