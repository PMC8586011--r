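#!/usr/bin/env Rscript
# Step 3: cross-sample nonredundant merge with variant-allele-balance
# genotyping (0/0 <= 0.2 < 0/1 <= 0.8 < 1/1), allele-frequency classing
# (singleton / rare / low / common), the population VCF, and the
# subsampling discovery curve.
suppressMessages(library(svpop))

sim <- readRDS("scratch/01_sim.rds")
per_sample <- readRDS("scratch/02_per_sample.rds")

popset <- merge_population(per_sample)
saveRDS(popset, "scratch/03_popset.rds")
write_population_vcf(popset, "results/03_population.vcf",
                     contigs = sim$genome$chrom_len)

cats <- as.data.frame(table(category = popset$svs$category,
                            sv_type = popset$svs$sv_type))
write.table(cats, "results/03_af_categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

curve <- subsample_curve(per_sample, sizes = seq(10, 50, by = 10),
                         reps = 2, seed = 104)
write.table(curve, "results/03_subsample_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(popset)
singles <- curve[curve$category == "singleton", ]
cat(sprintf(paste0(
  "Nonredundant set: %d SVs (truth had %d). Singleton count grows with\n",
  "sample size (%.0f at n=10 to %.0f at n=50) while common SVs stay\n",
  "stable — the discovery curve is far from saturation.\n"),
  nrow(popset$svs), nrow(sim$truth$svs),
  singles$mean_count[1], singles$mean_count[nrow(singles)]))
cat("Outputs: results/03_population.vcf, 03_af_categories.tsv,",
    "03_subsample_curve.tsv\n")
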