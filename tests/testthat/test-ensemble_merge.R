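test_that("reciprocal overlap follows the mutual-overlap definition", {
  a <- qcall(0, 100)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(qcall(0, 100), qcall(200, 100)), 0.0)
  expect_equal(reciprocal_overlap(qcall(0, 100), qcall(50, 100)), 0.5)
  # different type or chromosome: no affinity
  expect_equal(reciprocal_overlap(qcall(0, 100), qcall(0, 100, type = "INS")), 0)
  expect_equal(reciprocal_overlap(qcall(0, 100), qcall(0, 100, chrom = "chr2")), 0)
  bad <- qcall(0, 100); bad$end <- bad$start
  expect_error(reciprocal_overlap(bad, a), "zero-length")
})

test_that("reciprocal overlap is symmetric and matches arithmetic oracle", {
  set.seed(11)
  for (k in 1:50) {
    x <- rand_intervals(2)
    a <- x[1, ]; b <- x[2, ]
    expect_equal(reciprocal_overlap(a, b), reciprocal_overlap(b, a))
    expect_equal(reciprocal_overlap(a, b),
                 ro_oracle(a$start, a$end, b$start, b$end))
  }
})

test_that("partition into non-overlapping groups matches union-find oracle", {
  # three pairwise disjoint SVs -> three singleton groups
  x <- qcall(c(0, 200, 400), 50)
  expect_length(partition_components(x), 3)
  # chain A-B, B-C with A,C disjoint -> one transitive group
  y <- qcall(c(0, 80, 160), 100)
  expect_length(partition_components(y), 1)
  set.seed(23)
  for (k in 1:5) {
    z <- rand_intervals(200, span = 5000)
    got <- partition_components(z)
    want <- components_oracle(z)
    key <- function(d) paste(sort(paste(d$start, d$svlen)), collapse = ";")
    expect_setequal(unname(vapply(got, key, "")),
                    unname(vapply(want, function(i) key(z[i, ]), "")))
  }
})

test_that("CAST clustering handles cliques and isolates", {
  # near-identical intervals: a clique stays one cluster
  g <- qcall(c(0, 5, 10), 100, caller = c("sniffles", "nanovar", "nanosv"))
  expect_length(cast_cluster(g), 1)
  # A-B tight, C disjoint from both
  g2 <- qcall(c(0, 10, 500), c(100, 100, 80),
              caller = c("sniffles", "nanovar", "nanosv"))
  cl <- cast_cluster(g2)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, nrow, 1L), c(2L, 1L))
  expect_length(cast_cluster(empty_sv_calls()), 0)
})

test_that("CAST is deterministic and never mixes SV types across clusters", {
  set.seed(31)
  g <- rand_intervals(8, span = 300)
  expect_identical(cast_cluster(g), cast_cluster(g))
  pooled <- rbind(rand_intervals(10, span = 400),
                  rand_intervals(10, span = 400, type = "INS"))
  merged <- merge_within_sample(list(a = pooled), min_callers = 1)
  # re-cluster internals guarantee per-type grouping; check via pipeline
  clusters <- svpop:::.cluster_pooled(pooled)
  expect_true(all(vapply(clusters,
                         function(cl) length(unique(cl$sv_type)) == 1, TRUE)))
})

test_that("within-sample merge keeps >=2-caller consensus with priority", {
  sn <- qcall(100, 200, caller = "sniffles", support = 9)
  nv <- qcall(105, 210, caller = "nanovar", support = 12)
  ns_only <- qcall(5000, 150, caller = "nanosv")
  m <- merge_within_sample(list(sniffles = sn, nanovar = nv, nanosv = ns_only))
  expect_equal(nrow(m), 1)                      # lone-caller SV dropped
  expect_equal(m$caller_id, "sniffles")         # priority representative
  expect_equal(m$start, 100)
  expect_equal(m$support_reads, 9)              # support from representative
  expect_equal(m$n_callers, 2)
  # NanoVar + NanoSV without Sniffles: NanoVar representative
  m2 <- merge_within_sample(list(nanovar = nv, nanosv = qcall(102, 205,
                                                              caller = "nanosv")))
  expect_equal(m2$caller_id, "nanovar")
  # duplicate records collapse with a warning
  expect_warning(
    merge_within_sample(list(sniffles = rbind(sn, sn), nanovar = nv)),
    "duplicate")
})

test_that("noise-free three-caller merge reproduces truth exactly", {
  genome <- tiny_genome()
  truth <- simulate_population(sim_params(n_samples = 4, n_svs = 150,
                                          seed = 9), genome)
  profiles <- list(identity_caller_profile("sniffles"),
                   identity_caller_profile("nanovar"),
                   identity_caller_profile("nanosv"))
  cs <- simulate_callsets(truth, profiles, seed = 5)
  for (sid in names(cs)) {
    m <- merge_within_sample(cs[[sid]])
    carriers <- truth$svs[truth$genotypes[sid, ] >= 1, ]
    expect_equal(nrow(m), nrow(carriers))
    expect_true(all(m$n_callers == 3))
    o <- order(m$chrom, m$start); oc <- order(carriers$chrom, carriers$start)
    expect_equal(m$start[o], carriers$start[oc])
    expect_equal(m$svlen[o], carriers$svlen[oc])
  }
})

test_that("merging the merged representatives is idempotent", {
  set.seed(47)
  pooled <- rbind(rand_intervals(15, span = 2000, caller = "sniffles"),
                  rand_intervals(15, span = 2000, caller = "nanovar"))
  m1 <- merge_within_sample(list(a = pooled), min_callers = 1)
  m2 <- merge_within_sample(list(a = m1[, names(empty_sv_calls())]),
                            min_callers = 1)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(sort(m2$start), sort(m1$start))
  expect_equal(sort(m2$svlen), sort(m1$svlen))
})
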