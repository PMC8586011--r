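# hand-built single-gene model: + strand gene on chr1 spanning [10000, 20000)
# with CDS exons [11000,11500) and [15000,15500), UTRs flanking, promoter
# [9000, 10000)
toy_genes <- function() {
  list(genes = data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                          start = 10000, end = 20000,
                          promoter_start = 9000, promoter_end = 10000,
                          stringsAsFactors = FALSE),
       cds = data.frame(gene_id = "G1", chrom = "chr1",
                        start = c(11000, 15000), end = c(11500, 15500),
                        stringsAsFactors = FALSE),
       utr = data.frame(gene_id = "G1", chrom = "chr1",
                        start = c(10000, 19000), end = c(10500, 20000),
                        side = c("5", "3"), stringsAsFactors = FALSE))
}

test_that("coding-impact rules: DEL/INS/DUP/INV against CDS and whole gene", {
  g <- toy_genes()
  # 1 kb DEL clipping one exon by 10 bp
  expect_equal(classify_coding_impact(qcall(10010, 1000), g)$impact, "pLoF")
  # INS landing inside a CDS vs in an intron
  expect_equal(classify_coding_impact(qcall(11200, 300, type = "INS"), g)$impact,
               "pLoF")
  expect_equal(classify_coding_impact(qcall(12000, 300, type = "INS"), g)$impact,
               "none")
  # INS start exactly at a CDS boundary is not "directly into" the CDS
  expect_equal(classify_coding_impact(qcall(11000, 300, type = "INS"), g)$impact,
               "none")
  # DUP spanning the whole gene with margins: WDUP, not pLoF
  wd <- classify_coding_impact(qcall(5000, 20000, type = "DUP"), g)
  expect_equal(wd$impact, "WDUP")
  expect_equal(wd$whole_genes, "G1")
  expect_equal(wd$plof_genes, "")
  # INV partially overlapping a CDS: pLoF
  expect_equal(classify_coding_impact(qcall(11400, 2000, type = "INV"), g)$impact,
               "pLoF")
})

test_that("gene-feature precedence is CDS > UTR > promoter > intron", {
  g <- toy_genes()
  # start in 3' UTR, no CDS contact
  expect_equal(assign_gene_feature(qcall(19100, 2000), g), "UTR")
  # one breakpoint in the promoter, the other upstream; no CDS/UTR contact
  expect_equal(assign_gene_feature(qcall(8500, 700), g), "promoter")
  # spanning the entire gene including CDS: precedence forces CDS
  expect_equal(assign_gene_feature(qcall(9500, 12000), g), "CDS")
  # both breakpoints inside the gene between exons
  expect_equal(assign_gene_feature(qcall(12000, 500), g), "intron")
  expect_equal(assign_gene_feature(qcall(30000, 500), g), "intergenic")
  # feature labels partition any SV set
  set.seed(5)
  svs <- qcall(floor(runif(100, 0, 40000)), floor(runif(100, 50, 3000)))
  f <- assign_gene_feature(svs, g)
  expect_true(all(f %in% c("CDS", "UTR", "promoter", "intron", "intergenic")))
  expect_length(f, 100)
})

test_that("repeat classification uses the half-length and 7-bp-unit rules", {
  svs <- rbind(qcall(0, 300, type = "INS"),    # 280/300 Alu
               qcall(1000, 100),               # 40/100 below half
               qcall(2000, 100))               # tandem 60%, unit 7
  reps <- data.frame(
    chrom = "chr1",
    start = c(10, 1020, 2000),
    end = c(290, 1060, 2060),
    family = c("SINE/Alu", "SINE/Alu", "TRF"),
    unit_len = c(NA, NA, 7))
  got <- classify_repeat(svs, reps)
  expect_equal(got, c("family:SINE/Alu", "none", "VNTR"))
  # overlapping same-family annotations are unioned before coverage
  dup <- data.frame(chrom = "chr1", start = c(0, 100), end = c(160, 260),
                    family = "LINE/L1", unit_len = NA)
  expect_equal(classify_repeat(qcall(0, 300, type = "INS"), dup),
               "family:LINE/L1")
  # a tandem annotation with unit < 7 keeps its family name
  st <- data.frame(chrom = "chr1", start = 0, end = 80,
                   family = "Simple_repeat", unit_len = 4)
  expect_equal(classify_repeat(qcall(0, 100), st), "family:Simple_repeat")
})

test_that("feature enrichment matches the hypergeometric oracle", {
  # uniform table: no enrichment anywhere
  u <- matrix(100, 2, 2, dimnames = list(c("singleton", "common"),
                                         c("CDS", "intron")))
  resu <- feature_enrichment(u)
  expect_true(all(abs(resu$odds_ratio - 1) < 1e-6))
  expect_true(all(resu$p == 1))
  # 2x2 [10, 90; 10, 890] against direct hypergeometric enumeration
  tab <- matrix(c(10, 90, 10, 890), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("f", "g")))
  res <- feature_enrichment(tab)
  cell <- res[res$category == "a" & res$feature == "f", ]
  m <- 20; n_ <- 980; k <- 100   # margins of the 2x2
  probs <- dhyper(0:m, m, n_, k)
  p_oracle <- sum(probs[probs <= dhyper(10, m, n_, k) * (1 + 1e-7)])
  expect_equal(cell$p, p_oracle, tolerance = 1e-8)
  expect_equal(cell$p, fisher.test(tab)$p.value)
  # BH q-values are monotone and >= p
  expect_true(all(res$q >= res$p - 1e-12))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
})

test_that("singleton CDS enrichment direction matches the published margins", {
  # categories x {CDS, not-CDS}: singletons 1271 CDS of 56,239 vs the rest of
  # a 132,312-SV population with 2234 CDS SVs overall
  counts <- matrix(c(1271, 56239 - 1271,
                     2234 - 1271, (132312 - 56239) - (2234 - 1271)),
                   2, byrow = TRUE,
                   dimnames = list(c("singleton", "other"),
                                   c("CDS", "nonCDS")))
  res <- feature_enrichment(counts)
  cell <- res[res$category == "singleton" & res$feature == "CDS", ]
  expect_gt(cell$odds_ratio, 1)
  expect_lt(cell$q, 0.01)
})

test_that("planted pLoF deletions are recovered with precision and recall 1", {
  genome <- simulate_genome(n_chroms = 2, chrom_len = 3e6, n_genes = 14,
                            seed = 19)
  truth <- simulate_population(sim_params(n_samples = 6, n_svs = 200,
                                          n_plof = 8, seed = 3), genome)
  imp <- classify_coding_impact(truth$svs, genome$genes)
  expect_equal(imp$impact == "pLoF", truth$svs$plof)
})
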