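#' Mutual reciprocal overlap between two SV calls
#'
#' The merge affinity: shared interval length divided by the length of each
#' call, taking the minimum of the two fractions, i.e.
#' `min(ov/len_a, ov/len_b)`. Calls on different chromosomes or of different
#' SV types have affinity 0. INS calls use the synthetic interval
#' `[start, start + svlen)`, which makes the affinity sensitive to both
#' position and length.
#'
#' @param a,b single SV calls (one-row data frames or lists with fields
#'   `chrom`, `sv_type`, `start`, `end`).
#' @return overlap fraction in `[0, 1]`.
#' @export
#' @examples
#' a <- sv_calls("s", "sniffles", "DEL", "chr1", 0, 100, 5, 10)
#' b <- sv_calls("s", "nanovar", "DEL", "chr1", 50, 100, 5, 10)
#' reciprocal_overlap(a, b)  # 0.5
reciprocal_overlap <- function(a, b) {
  la <- a$end - a$start
  lb <- b$end - b$start
  if (la <= 0 || lb <= 0) stop("zero-length interval")
  if (a$chrom != b$chrom || a$sv_type != b$sv_type) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  ov / max(la, lb)
}

# Pairwise affinity matrix for calls on one chromosome / one type.
# RO(i, j) = overlap / max(len_i, len_j); diagonal 1.
.affinity_matrix <- function(df) {
  s <- df$start; e <- df$end
  ov <- pmax(0, outer(e, e, pmin) - outer(s, s, pmax))
  len <- e - s
  A <- ov / outer(len, len, pmax)
  diag(A) <- 1
  A
}

#' Partition calls into non-overlapping groups
#'
#' Connected components of the graph whose edges join interval-intersecting
#' pairs (any >= 1 bp overlap). Because the objects are intervals, a single
#' sorted sweep recovers the transitive closure exactly.
#'
#' @param svs `sv_calls` data frame, all on one chromosome and of one type.
#' @return list of data frames; disjoint groups covering the input.
#' @export
partition_components <- function(svs) {
  idx <- .partition_indices(svs)
  lapply(idx, function(i) svs[i, , drop = FALSE])
}

.partition_indices <- function(svs) {
  n <- nrow(svs)
  if (n == 0) return(list())
  if (length(unique(svs$chrom)) > 1 || length(unique(svs$sv_type)) > 1)
    stop("partition_components expects a single chromosome and SV type")
  ord <- order(svs$start, svs$end)
  s <- svs$start[ord]; e <- svs$end[ord]
  grp <- integer(n)
  g <- 1L; reach <- e[1]; grp[1] <- 1L
  for (i in seq_len(n)[-1]) {
    if (s[i] >= reach) { g <- g + 1L; reach <- e[i] } else reach <- max(reach, e[i])
    grp[i] <- g
  }
  split(ord, grp)
}

#' CAST clustering of one overlap group
#'
#' Greedy Cluster Affinity Search Technique over the corrupted-clique model:
#' open a new cluster seeded with the unassigned node of maximal degree
#' (edges = pairs with affinity >= `threshold`), then alternately ADD the
#' unassigned element whose mean affinity to the cluster is maximal (if that
#' mean is >= `threshold`) and REMOVE the member whose mean affinity to the
#' other members is minimal (if that mean is < `threshold`), until stable;
#' close the cluster and repeat. Deterministic: all ties are broken by
#' (smaller start, longer svlen, caller priority).
#'
#' @param group `sv_calls` data frame from [partition_components()].
#' @param threshold affinity threshold (default 0.5 = 50% mutual overlap).
#' @return list of data frames (clusters). Each carries a logical attribute
#'   `cast_flag`: TRUE when some member pair falls below `threshold` and was
#'   admitted by the average-affinity rule.
#' @export
cast_cluster <- function(group, threshold = 0.5) {
  n <- nrow(group)
  if (n == 0) return(list())
  A <- .affinity_matrix(group)
  pref <- .pref_rank(group)
  unassigned <- rep(TRUE, n)
  edges <- A >= threshold
  clusters <- list()
  while (any(unassigned)) {
    idx <- which(unassigned)
    deg <- rowSums(edges[idx, idx, drop = FALSE]) - 1
    seed <- idx[.pick(deg, pref[idx], maximize = TRUE)]
    C <- seed
    iter <- 0L
    repeat {
      iter <- iter + 1L
      changed <- FALSE
      # ADD
      out <- setdiff(which(unassigned), C)
      if (length(out)) {
        avg <- colMeans(A[C, out, drop = FALSE])
        if (max(avg) >= threshold) {
          C <- c(C, out[.pick(avg, pref[out], maximize = TRUE)])
          changed <- TRUE
        }
      }
      # REMOVE
      if (length(C) > 1) {
        avgm <- vapply(seq_along(C), function(k)
          mean(A[C[-k], C[k]]), numeric(1))
        if (min(avgm) < threshold) {
          # ties: remove the least-preferred member
          C <- C[-.pick(-avgm, -pref[C], maximize = TRUE)]
          changed <- TRUE
        }
      }
      if (!changed || iter > 100L + 10L * n) break
    }
    unassigned[C] <- FALSE
    clusters[[length(clusters) + 1L]] <- sort(C)
  }
  lapply(clusters, function(i) {
    cl <- group[i, , drop = FALSE]
    sub <- A[i, i, drop = FALSE]
    attr(cl, "cast_flag") <- any(sub < threshold)
    cl
  })
}

# index of the best element: maximal (or minimal) score, ties by smaller
# preference rank
.pick <- function(score, pref, maximize = TRUE) {
  if (!maximize) score <- -score
  cand <- which(score == max(score))
  cand[which.min(pref[cand])]
}

#' Merge one sample's callsets from multiple callers
#'
#' Pools the callers' calls per SV type and chromosome, partitions them into
#' non-overlapping groups, CAST-clusters each group at 50% mutual overlap,
#' and keeps clusters supported by at least `min_callers` distinct callers.
#' The representative is the member from the highest-priority caller present
#' (Sniffles, then NanoVar, then NanoSV); its support and depth become the
#' merged call's support and depth.
#'
#' @param callsets named list `caller -> sv_calls` for one sample.
#' @param min_callers minimum number of distinct callers per cluster.
#' @param threshold CAST affinity threshold.
#' @return `sv_calls` data frame of representatives with extra columns
#'   `n_callers` and `caller_support` (comma-joined caller ids).
#' @export
merge_within_sample <- function(callsets, min_callers = 2, threshold = 0.5) {
  pooled <- .bind_calls(callsets)
  if (nrow(pooled) == 0) {
    out <- empty_sv_calls()
    out$n_callers <- integer(); out$caller_support <- character()
    return(out)
  }
  if (length(unique(pooled$sample_id)) > 1)
    stop("merge_within_sample expects calls from a single sample")
  dup <- duplicated(pooled[, c("caller_id", "sv_type", "chrom", "start", "svlen")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (caller, record) call(s) collapsed")
    pooled <- pooled[!dup, , drop = FALSE]
  }
  clusters <- .cluster_pooled(pooled, threshold)
  kept <- Filter(function(cl) length(unique(cl$caller_id)) >= min_callers, clusters)
  if (!length(kept)) {
    out <- empty_sv_calls()
    out$n_callers <- integer(); out$caller_support <- character()
    return(out)
  }
  reps <- do.call(rbind, lapply(kept, function(cl) {
    pr <- match(cl$caller_id, .CALLERS)
    best <- which(pr == min(pr))
    best <- best[which.min(.pref_rank(cl)[best])]
    rep <- cl[best, .SV_COLS, drop = FALSE]
    rep$n_callers <- length(unique(cl$caller_id))
    rep$caller_support <- paste(intersect(.CALLERS, unique(cl$caller_id)),
                                collapse = ",")
    rep
  }))
  reps <- reps[order(reps$chrom, reps$start, reps$sv_type), , drop = FALSE]
  rownames(reps) <- NULL
  class(reps) <- unique(c("sv_calls", class(reps)))
  reps
}

# Partition + CAST over a pooled call table, per (type, chrom).
# Returns a flat list of cluster data frames.
.cluster_pooled <- function(pooled, threshold = 0.5) {
  keys <- paste(pooled$sv_type, pooled$chrom)
  out <- list()
  for (k in sort(unique(keys))) {
    sub <- pooled[keys == k, , drop = FALSE]
    for (grp in .partition_indices(sub)) {
      out <- c(out, cast_cluster(sub[grp, , drop = FALSE], threshold))
    }
  }
  out
}
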