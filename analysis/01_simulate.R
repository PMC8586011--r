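#!/usr/bin/env Rscript
# Step 1: build the study's synthetic inputs — a toy genome (3 x 20 Mb with
# centromere/gap/high-depth masks and 60 protein-coding genes), a truth SV
# population for 50 diploid samples (5,000 loci, DEL/INS-dominated type mix,
# bimodal indel lengths, singleton-heavy SFS, 20 planted pLoF deletions),
# and three imperfect caller callsets at 15x depth.
suppressMessages(library(svpop))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

genome <- simulate_genome(chrom_len = 2e7, seed = 101)
params <- sim_params(n_samples = 50, n_svs = 5000, n_plof = 20, seed = 102)
truth <- simulate_population(params, genome)
callsets <- simulate_callsets(truth, default_caller_profiles(), seed = 103)

saveRDS(list(genome = genome, truth = truth, callsets = callsets),
        "scratch/01_sim.rds")

# standard-format views of the inputs (one sample's worth)
dir.create("results/example_inputs", showWarnings = FALSE)
write_gene_models_gtf(genome$genes, "results/example_inputs/genes.gtf")
for (lab in unique(genome$masks$label))
  write_region_bed(genome$masks[genome$masks$label == lab, ],
                   sprintf("results/example_inputs/%s.bed", lab))
for (cl in names(callsets[[1]]))
  write_caller_vcf(callsets[[1]][[cl]],
                   sprintf("results/example_inputs/S001.%s.vcf", cl),
                   contigs = genome$chrom_len)

summ <- data.frame(
  metric = c("n_samples", "n_truth_svs", "DEL", "INS", "DUP", "INV",
             "median_len_bp", "len_peak_300bp_frac", "len_peak_6kb_frac",
             "planted_plof", "mean_calls_per_sample_per_caller"),
  value = c(params$n_samples, nrow(truth$svs),
            as.numeric(table(truth$svs$sv_type)[c("DEL", "INS", "DUP", "INV")]),
            median(truth$svs$svlen),
            round(mean(truth$svs$svlen > 250 & truth$svs$svlen < 350), 3),
            round(mean(truth$svs$svlen > 5000 & truth$svs$svlen < 7000), 3),
            sum(truth$svs$plof),
            round(mean(vapply(callsets, function(s)
              mean(vapply(s, nrow, 1L)), numeric(1))), 1)))
write.table(summ, "results/01_truth_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Truth population simulated:", nrow(truth$svs), "SVs across",
    params$n_samples, "samples;",
    round(mean(vapply(callsets, function(s) mean(vapply(s, nrow, 1L)),
                      numeric(1)))),
    "calls per sample per caller on average.\n")
cat("Summary written to results/01_truth_summary.tsv\n")
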