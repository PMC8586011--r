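test_that("toy genome generation is deterministic and self-consistent", {
  g1 <- simulate_genome(seed = 8)
  g2 <- simulate_genome(seed = 8)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$masks, g2$masks)
  expect_equal(nrow(g1$genes$genes), 60)
  # genes (with promoter flank) never intersect masks
  gg <- g1$genes$genes
  for (i in seq_len(nrow(gg))) {
    m <- g1$masks[g1$masks$chrom == gg$chrom[i], ]
    expect_false(any(gg$start[i] < m$end & m$start < gg$end[i]))
  }
})

test_that("simulated populations honor the type mix and HWE structure", {
  genome <- simulate_genome(chrom_len = 2e7, seed = 4)
  params <- sim_params(n_samples = 40, n_svs = 10000, seed = 6)
  truth <- simulate_population(params, genome)
  frac <- table(truth$svs$sv_type)[c("DEL", "INS", "DUP", "INV")] / 10000
  expect_true(all(abs(frac - params$type_mix) < 0.01))
  # bimodal indel lengths: mass near 300 bp and near 6 kb
  len <- truth$svs$svlen
  expect_gt(mean(len > 250 & len < 350), 0.2)
  expect_gt(mean(len > 5000 & len < 7000), 0.03)
  # every locus has at least one carrier
  expect_true(all(colSums(truth$genotypes) >= 1))
  # F = 0: subpopulation frequency equals the ancestral draw
  expect_equal(unname(truth$p_group[1, ]), truth$svs$p_anc)
})

test_that("Balding-Nichols divergence produces distinct subpop frequencies", {
  genome <- tiny_genome(seed = 14)
  sp <- data.frame(group = c("north", "south"), n = c(10, 10), F = 0.2)
  truth <- simulate_population(sim_params(n_samples = 20, n_svs = 300,
                                          subpops = sp, seed = 2), genome)
  expect_equal(dim(truth$p_group), c(2, 300))
  expect_gt(sd(truth$p_group[1, ] - truth$p_group[2, ]), 0.05)
  expect_equal(truth$samples$group, rep(c("north", "south"), each = 10))
})

test_that("identity caller profile reproduces truth carriers exactly", {
  genome <- tiny_genome(seed = 25)
  truth <- simulate_population(sim_params(n_samples = 5, n_svs = 100,
                                          seed = 12), genome)
  calls <- simulate_caller_calls(truth, identity_caller_profile(), seed = 3)
  for (sid in names(calls)) {
    carriers <- truth$svs[truth$genotypes[sid, ] >= 1, ]
    cc <- calls[[sid]]
    expect_equal(nrow(cc), nrow(carriers))
    o <- order(cc$chrom, cc$start); ot <- order(carriers$chrom, carriers$start)
    expect_equal(cc$start[o], carriers$start[ot])
    expect_equal(cc$svlen[o], carriers$svlen[ot])
    expect_equal(cc$truth_id[o], carriers$sv_id[ot])
  }
})

test_that("false-positive load is Poisson and avoids truth loci", {
  genome <- tiny_genome(seed = 33)
  truth <- simulate_population(sim_params(n_samples = 2, n_svs = 40,
                                          seed = 18), genome)
  prof <- identity_caller_profile()
  prof$fp_rate <- 100
  prof$sensitivity[] <- 0   # only false calls remain
  counts <- vapply(1:20, function(k) {
    calls <- simulate_caller_calls(truth, prof, seed = 100 + k)
    nrow(calls[[1]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 20))
  # no false call reaches 50% reciprocal overlap with truth
  calls <- simulate_caller_calls(truth, prof, seed = 7)
  expect_false(any(match_reciprocal(calls[[1]], truth$svs, strict = FALSE)$matched))
})

test_that("breakpoint jitter at sd 15 rarely breaks 300-bp overlap", {
  # N(0, 15) start shift on a 300 bp SV: reciprocal overlap stays > 0.5
  # unless |shift| > 150; P ~ 2 * pnorm(-10) is negligible, so >= 99% of
  # emitted calls must still match their truth locus
  genome <- simulate_genome(chrom_len = 5e6, n_genes = 12, seed = 41)
  params <- sim_params(n_samples = 6, n_svs = 500,
                       length_model = list(weights = c(alu = 1),
                                           alu_mean = 300, alu_sd = 1,
                                           min_len = 50, max_len = 1e5),
                       seed = 29)
  truth <- simulate_population(params, genome)
  prof <- identity_caller_profile()
  prof$breakpoint_jitter_sd <- 15
  calls <- simulate_caller_calls(truth, prof, seed = 55)
  all_calls <- do.call(rbind, calls)
  hit <- logical(nrow(all_calls))
  ti <- match(all_calls$truth_id, truth$svs$sv_id)
  for (k in seq_len(nrow(all_calls)))
    hit[k] <- ro_oracle(all_calls$start[k], all_calls$end[k],
                        truth$svs$start[ti[k]], truth$svs$end[ti[k]]) > 0.5
  expect_gt(mean(hit), 0.99)
})

test_that("caller emulation is byte-deterministic under a fixed seed", {
  genome <- tiny_genome(seed = 9)
  truth <- simulate_population(sim_params(n_samples = 3, n_svs = 60,
                                          seed = 10), genome)
  prof <- default_caller_profiles()$sniffles
  c1 <- simulate_caller_calls(truth, prof, seed = 77)
  c2 <- simulate_caller_calls(truth, prof, seed = 77)
  expect_identical(c1, c2)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_caller_vcf(c1[[1]], f1, contigs = genome$chrom_len)
  write_caller_vcf(c2[[1]], f2, contigs = genome$chrom_len)
  expect_identical(readLines(f1), readLines(f2))
})
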