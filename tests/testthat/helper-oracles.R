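# Independent oracles and small fixture builders shared across tests.

# shorthand call constructor on one chromosome/type
qcall <- function(start, svlen, type = "DEL", caller = "sniffles",
                  sample = "s1", chrom = "chr1", support = 10, depth = 15) {
  sv_calls(sample_id = sample, caller_id = caller, sv_type = type,
           chrom = chrom, start = start, svlen = svlen,
           support_reads = support, site_depth = depth)
}

rand_intervals <- function(n, span = 1000, len_min = 20, len_max = 200,
                          type = "DEL", caller = "sniffles") {
  start <- floor(runif(n, 0, span))
  len <- floor(runif(n, len_min, len_max))
  qcall(start, len, type = type, caller = caller)
}

# plain-arithmetic reciprocal overlap, written independently of the package
ro_oracle <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# O(n^2) union-find over all interval-intersecting pairs
components_oracle <- function(svs) {
  n <- nrow(svs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && svs$start[i] < svs$end[j] && svs$start[j] < svs$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  if (n == 0) return(list())
  parts <- list(c(1L))
  for (k in seq_len(n - 1)) {
    parts <- do.call(c, lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(b) c(p, b))
    }))
  }
  parts
}

# corrupted-clique score of a partition: within-cluster affinities centered
# at the threshold count positively, cross-cluster ones negatively
partition_score <- function(A, labels, threshold = 0.5) {
  n <- nrow(A); sc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      w <- A[i, j] - threshold
      sc <- sc + if (labels[i] == labels[j]) w else -w
    }
  }
  sc
}

cast_score <- function(group, clusters, threshold = 0.5) {
  A <- svpop:::.affinity_matrix(group)
  labels <- integer(nrow(group))
  key <- paste(group$start, group$svlen, group$caller_id)
  for (k in seq_along(clusters)) {
    ck <- paste(clusters[[k]]$start, clusters[[k]]$svlen,
                clusters[[k]]$caller_id)
    labels[key %in% ck] <- k
  }
  partition_score(A, labels, threshold)
}

best_partition_score <- function(group, threshold = 0.5) {
  A <- svpop:::.affinity_matrix(group)
  max(vapply(all_partitions(nrow(group)),
             function(lab) partition_score(A, lab, threshold), numeric(1)))
}

# per-sample callsets taken directly from truth genotypes (noise-free,
# single caller), with binomial support at the truth depth
truth_callsets_vab <- function(truth, caller = "sniffles") {
  G <- truth$genotypes
  svs <- truth$svs
  depth <- truth$params$depth
  out <- list()
  for (i in seq_len(nrow(G))) {
    idx <- which(G[i, ] >= 1)
    dep <- rep(depth, length(idx))
    sup <- rbinom(length(idx), dep, ifelse(G[i, idx] == 1, 0.5, 1.0))
    sup <- pmax(1, sup)
    out[[rownames(G)[i]]] <- qcall(svs$start[idx], svs$svlen[idx],
                                   type = svs$sv_type[idx],
                                   chrom = svs$chrom[idx],
                                   sample = rownames(G)[i],
                                   support = sup, depth = dep)
  }
  out
}

tiny_genome <- function(seed = 7) simulate_genome(n_chroms = 2,
                                                  chrom_len = 2e6,
                                                  n_genes = 10, seed = seed)
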