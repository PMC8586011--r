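vcf_header_min <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1,length=1000000>",
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
  '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
  '##INFO=<ID=RE,Number=1,Type=Integer,Description="r">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
        collapse = "\t"))

test_that("caller VCF reading normalizes coordinates and conventions", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header_min,
               "chr1\t1001\tx1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300;RE=7",
               "chr1\t5001\tx2\tN\t<BND>\t.\tPASS\tSVTYPE=BND;SVLEN=100",
               "chr1\t9001\tx3\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=250;RE=4"),
             f)
  calls <- suppressMessages(read_caller_vcf(f, "sniffles", "s1"))
  expect_equal(nrow(calls), 2)       # BND dropped
  expect_equal(calls$start[1], 1000) # 1-based POS -> 0-based start
  expect_equal(calls$end[1], 1300)
  expect_equal(calls$svlen[1], 300)  # negative SVLEN folded to length
  expect_equal(calls$support_reads, c(7, 4))
  expect_equal(calls$end[2], 9000 + 250)  # INS synthetic interval
})

test_that("header-only and absent-SVTYPE records are handled", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_header_min, f)
  expect_equal(nrow(suppressWarnings(read_caller_vcf(f, "sniffles", "s"))), 0)
  writeLines(c(vcf_header_min,
               "chr1\t100\ty\tN\t<DEL>\t.\tPASS\tSVLEN=-50",
               "chr1\t500\tz\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-60;RE=3"),
             f)
  expect_warning(calls <- read_caller_vcf(f, "sniffles", "s"), "SVTYPE")
  expect_equal(nrow(calls), 1)
  expect_error(suppressWarnings(read_caller_vcf(tempfile(), "sniffles", "s")))
})

test_that("caller VCFs round-trip through every dialect", {
  set.seed(14)
  for (dialect in c("sniffles", "nanovar", "nanosv", "truth")) {
    n <- 50
    calls <- sv_calls(sample_id = "s7", caller_id = dialect,
                      sv_type = sample(c("DEL", "INS", "DUP", "INV"), n, TRUE),
                      chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sort(floor(runif(n, 0, 9e5))),
                      svlen = floor(runif(n, 50, 5000)),
                      support_reads = rbinom(n, 15, 0.6),
                      site_depth = 15)
    calls <- calls[order(calls$chrom, calls$start, calls$sv_type), ]
    rownames(calls) <- NULL
    f <- tempfile(fileext = ".vcf")
    write_caller_vcf(calls, f, contigs = c(chr1 = 1e6, chr2 = 1e6))
    back <- read_caller_vcf(f, dialect, "s7")
    expect_equal(back, calls, ignore_attr = TRUE)
  }
})

test_that("population VCF writes AC/AN/AF and round-trips genotypes", {
  per_sample <- list(
    s1 = qcall(1000, 300, sample = "s1", support = 8, depth = 15),
    s2 = qcall(1000, 300, sample = "s2", support = 15, depth = 15))
  pop <- merge_population(per_sample)
  f <- tempfile(fileext = ".vcf")
  write_population_vcf(pop, f)
  line <- grep("^chr", readLines(f), value = TRUE)
  expect_match(line, "AC=3;AN=4;AF=0.75")     # 0/1 + 1/1
  back <- read_population_vcf(f)
  expect_equal(back$genotypes, pop$genotypes)
  expect_equal(back$svs$AC, pop$svs$AC)
  expect_equal(back$svs$category, pop$svs$category)
  # duplicate ids refuse to serialize
  two <- merge_population(list(
    s1 = qcall(c(1000, 9000), 300, sample = "s1", support = 8, depth = 15)))
  two$svs$sv_id[] <- "SV1"
  expect_error(write_population_vcf(two, f), "duplicate")
})

test_that("a simulated population round-trips through VCF", {
  genome <- tiny_genome(seed = 3)
  truth <- simulate_population(sim_params(n_samples = 8, n_svs = 200,
                                          seed = 31), genome)
  set.seed(6)
  pop <- merge_population(truth_callsets_vab(truth))
  f <- tempfile(fileext = ".vcf")
  write_population_vcf(pop, f, contigs = genome$chrom_len)
  back <- read_population_vcf(f)
  expect_equal(back$svs$start, pop$svs$start)
  expect_equal(back$svs$svlen, pop$svs$svlen)
  expect_equal(back$svs$sv_type, pop$svs$sv_type)
  expect_equal(back$genotypes, pop$genotypes)
  # INS synthetic ends preserved via SVLEN despite END = POS convention
  ins <- back$svs$sv_type == "INS"
  expect_equal(back$svs$end[ins], back$svs$start[ins] + back$svs$svlen[ins])
})

test_that("gene models round-trip through GTF with strand-aware promoters", {
  gtf <- tempfile(fileext = ".gtf")
  genes <- list(
    genes = data.frame(gene_id = c("GA", "GB", "GC"),
                       chrom = c("chr1", "chr1", "chr2"),
                       strand = c("+", "-", "+"),
                       start = c(10000, 50000, 20000),
                       end = c(20000, 60000, 26000),
                       promoter_start = c(9000, 60000, 19000),
                       promoter_end = c(10000, 61000, 20000),
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = c("GA", "GA", "GB", "GC"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     start = c(11000, 15000, 52000, 21000),
                     end = c(11500, 15500, 52600, 21900),
                     stringsAsFactors = FALSE),
    utr = data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                     start = c(10000, 59000), end = c(10400, 60000),
                     side = c("5", "5"), stringsAsFactors = FALSE))
  write_gene_models_gtf(genes, gtf)
  back <- read_gene_models(gtf)
  expect_equal(nrow(back$genes), 3)
  expect_equal(back$genes[order(back$genes$gene_id), ]$promoter_start,
               c(9000, 60000, 19000))
  # + strand TSS 10000 -> promoter [9000, 10000); - strand TSS at span end
  expect_equal(back$genes$promoter_end[back$genes$gene_id == "GB"], 61000)
  expect_equal(sum(back$cds$gene_id == "GA"), 2)
  expect_equal(back$cds[back$cds$gene_id == "GC", ]$start, 21000)
})

test_that("region BED and external TSV round-trips preserve coordinates", {
  masks <- data.frame(label = "gap", chrom = c("chr1", "chr2"),
                      start = c(100, 5000), end = c(400, 5600))
  bed <- tempfile(fileext = ".bed")
  write_region_bed(masks, bed)
  back <- read_region_bed(bed, label = "gap")
  expect_equal(back$start, masks$start)
  expect_equal(back$end, masks$end)
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", start = c(0, 100), end = c(60, 101),
                   type = c("DEL", "MEI"), svlen = c(60, 300))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ref <- read_external_sv_tsv(tsv)
  expect_equal(ref$sv_type, c("DEL", "INS"))
  expect_equal(ref$end, c(60, 400))   # INS synthetic end from svlen
})
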