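Package: svpop
Title: Population-Scale Structural Variant Merging, Genotyping and Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for long-read structural variant (SV)
    callsets across a population: multi-caller ensemble merging by mutual
    reciprocal overlap using CAST (Cluster Affinity Search Technique)
    clustering on the corrupted-clique model, support/length/region quality
    filtering, variant-allele-balance genotyping, population-level
    nonredundant merging with allele-frequency classing, coding-impact and
    gene-feature annotation, comparison against external SV sets (novelty,
    recall, false discovery rate), meta-chromosome density profiles, and
    population differentiation scans (Hudson F_ST, population branch
    statistic, identity-by-state kinship). Includes a seedable simulator of
    truth SV populations under the Balding-Nichols model and of imperfect
    caller callsets, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
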