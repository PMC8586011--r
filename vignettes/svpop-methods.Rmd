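---
title: "Population-scale SV merging, genotyping and differentiation: methods"
author: "svpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale SV merging, genotyping and differentiation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpop)
```

# Overview

`svpop` post-processes long-read structural-variant (SV) callsets across a
cohort. The pipeline takes per-sample calls from several SV callers and
produces a nonredundant, genotyped population SV set, then annotates it,
evaluates it against reference sets, and scans it for population
differentiation. Because cohort-scale long-read data are rarely shareable,
the package ships a seedable simulator that generates truth SV populations
and imperfect caller callsets with known ground truth; every stage of the
pipeline is validated against that truth.

The canonical SV types are deletions (DEL), insertions (INS), duplications
(DUP) and inversions (INV), each at least 50 bp. Breakends/translocations
are outside the model and are dropped at the VCF boundary.

# Coordinates and the insertion convention

All internal coordinates are 0-based half-open; VCF input/output converts
at the boundary (`POS = start + 1`). For DEL/DUP/INV the interval is the
reference footprint and `end - start = svlen`. An insertion's reference
footprint is a point, which breaks interval arithmetic, so INS records use
a *synthetic* interval `[start, start + svlen)` everywhere: in merge
affinities, region filtering and external comparison. This makes INS-INS
affinity sensitive to both position and length, which is intended — two
insertions at the same spot with very different lengths should not merge.
When a population VCF is written, `END` follows VCF convention (`POS` for
INS) and the synthetic end is preserved in the `INSEND` INFO tag.

# Ensemble merging (CAST on the corrupted-clique model)

Within a sample, the callers' calls are pooled per SV type and chromosome
and segregated into non-overlapping groups (connected components of the
interval-intersection graph; computed by a sorted sweep, which is exact for
intervals). Each group is clustered with the Cluster Affinity Search
Technique (CAST), treating the true co-reference relation as a corrupted
clique graph. The affinity between two calls is their mutual reciprocal
overlap

$$\mathrm{RO}(a, b) = \frac{|a \cap b|}{\max(|a|, |b|)},$$

i.e. the shared length as a fraction of the *longer* call, so both calls
must be covered at least 50% for the affinity to reach the 0.5 threshold.

CAST is a greedy heuristic; the original description leaves seeding, order
of operations and tie-breaks open, so the implementation fixes them for
reproducibility:

* a new cluster is seeded with the unassigned node of maximal degree
  (edges are pairs with affinity at or above the threshold);
* ADD is evaluated before REMOVE in each iteration: the unassigned element
  with maximal mean affinity to the cluster joins if that mean is
  >= 0.5; then the member with minimal mean affinity to the other members
  leaves if that mean is < 0.5;
* all ties are broken by (smaller start, longer `svlen`, caller priority);
* an iteration cap (`100 + 10n`) guards against add/remove oscillation,
  after which the cluster is closed as-is. In practice the cap is never
  reached on interval affinities.

Clusters supported by at least two distinct callers are kept. The
representative is the member from the highest-priority caller — Sniffles,
then NanoVar, then NanoSV, reflecting their relative benchmark performance
on ONT reads — and the representative's supporting-read count and site
depth carry forward to genotyping. The acceptance suite checks CAST
against an exhaustive search over all set partitions of groups of up to
six calls, scoring partitions by the corrupted-clique objective (affinities
centered at the threshold, within-cluster minus cross-cluster); CAST
attains the optimum in well over 90% of random groups. The score must be
threshold-centered: with raw affinities the optimum is degenerate, since
any positive affinity always rewards merging.

# Filtering cascade

Three filters run in order, with per-step removal accounting:

1. **Support**: at least 3 supporting reads. A depth-scaled mode is
   provided (`threshold = round(ratio x mean depth)`; ratio 0.2 equals 3
   reads at 15x) for depth-titration experiments; the fixed 3-read
   threshold is the production default.
2. **Length**: DEL/INS longer than 2 Mb and DUP/INV longer than 5 Mb are
   discarded, as is anything under 50 bp.
3. **Region**: any call intersecting a centromere, assembly-gap ("N") or
   high-depth (>= 500x) mask by at least 1 bp is discarded — the BEDTools
   default intersection semantics, since no overlap fraction is specified
   for this step. The length and region filters commute; the support
   filter commutes with both.

# Genotyping and the population set

Genotypes come from the variant allele balance (VAB), supporting reads
over site depth, with fixed cut points:

| VAB | genotype |
|---|---|
| <= 0.2 | 0/0 |
| (0.2, 0.8] | 0/1 |
| > 0.8 | 1/1 |
| depth 0 or unknown | ./. |

The bands are closed exactly as written (a VAB of exactly 0.2 is 0/0, of
exactly 0.8 is 0/1); the tests verify every support/depth pair up to depth
100. Under the binomial support model at 15x (het p = 0.5, hom p = 1.0)
the genotype concordance is about 98% — the residual errors are
heterozygotes drawn into the tails of Binomial(15, 0.5).

Across samples, filtered calls are merged with the same CAST machinery.
Each cluster becomes one population SV; the representative is the member
whose `(start, svlen)` pair occurs in the most samples ("most common in
the population"), with ties broken by higher support then smaller start
(the source convention is silent here). Samples with no member in the
cluster are genotyped 0/0 rather than missing — matching the use of the
full cohort in allele-frequency denominators — and `./.` is reserved for
members with unknown depth. A sample contributing two members keeps the
higher-support one. Clusters whose genotypes carry no alternate allele
(possible when every member's VAB falls at or below 0.2) are retained with
`category = NA` rather than silently dropped; the discovery-curve counts
use the polymorphic subset.

Allele statistics are `AC` (alt alleles over non-missing genotypes),
`AN = 2 x non-missing samples`, `AF = AC/AN`, `MAF = min(AF, 1 - AF)`, and
the frequency categories are: singleton (`AC = 1`), rare
(`AC > 1` and `AF <= 0.01`), low (`0.01 < AF <= 0.05`), common
(`AF > 0.05`). Note a scale effect: with 50 diploid samples (`AN = 100`)
the rare class is empty by arithmetic (`AC > 1` forces `AF > 0.01`); the
class only populates at cohort sizes in the hundreds, as in the
subsampling analyses.

The subsampling discovery curve re-merges random sample subsets at a grid
of sizes (several replicates per size, averaged) and counts nonredundant
SVs per category — singletons keep growing with cohort size while common
SVs saturate quickly.

# Annotation

Gene features are assigned with precedence CDS > UTR > promoter > intron >
intergenic. The CDS label requires interval intersection with a coding
exon; UTR and promoter labels are *breakpoint*-based (a breakpoint is the
start or end position; "in" means `s <= p < e`), conditioned on not
touching the higher-precedence features; intron requires both breakpoints
inside one gene's span; everything else is intergenic. Promoters are the
1 kb strand-aware region directly preceding the TSS, clipped at the
chromosome start.

Predicted loss-of-function (pLoF): a DEL overlapping at least one CDS; an
INS whose start lies strictly inside a CDS (a start exactly on the exon
boundary does not count as "directly into" the CDS — the boundary policy
is ours); a DUP/INV partially overlapping a CDS of a gene it does not
fully contain. A DUP/INV containing an entire gene span (TSS to TES, not
the transcript union) is WDUP/WINV for that gene and is not counted as
gene-disruptive; one call can be WDUP for one gene and pLoF for another,
in which case the record lists both and the summary impact is pLoF.

Repeat classification consumes a precomputed repeat-interval table
(RepeatMasker/TRF output parsed to TSV; running those tools is out of
scope). Same-family intervals are unioned inside the SV, the family
covering more than half the SV length wins, and a winning tandem-repeat
annotation with unit length >= 7 bp is relabelled VNTR.

Feature enrichment per frequency category uses a 2x2 two-sided Fisher
exact test per (category, feature) cell against the rest of the population
— the enrichment universe is all SVs in the set — with Benjamini-Hochberg
correction across cells; zero-margin cells are skipped with `q = NA`.

# Comparison and FDR

External reference sets are normalized first: CNV gains/losses map to
DUP/DEL, mobile-element insertions to INS, INS records without a usable
length are excluded (the reciprocal-overlap test needs both position and
length), and INS ends are rebuilt as `start + svlen`. A query SV matches a
reference record of the same type when the reciprocal overlap is *larger
than* 50% — strict, per the published comparison convention — while the
merge step uses *at least* 50%; both thresholds are independently
configurable. Novelty is assessed against the union of all references.
Recall is the matched fraction of the reference; FDR is the unmatched
fraction of the calls against a truth set, reported overall and per type
to one decimal percent.

# Population differentiation

Per-SV F_ST uses Hudson's estimator with sample-size correction,

$$\hat F_{ST} = \frac{(p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2 - 1}}{p_1(1-p_2) + p_2(1-p_1)},$$

clamped to `[0, 1)` (negative estimates to 0; a zero denominator gives
NA). For multi-locus summaries the package exposes the ratio-of-sums
combination (`hudson_fst_multi`), which is the calibrated way to average
Hudson F_ST across loci — the mean of per-site ratios is biased low.

The population branch statistic for focal population A against sister B
and outgroup C is

$$\mathrm{PBS}_A = \tfrac{1}{2}\left[-\ln(1 - F_{AB}) - \ln(1 - F_{AC}) + \ln(1 - F_{BC})\right],$$

clamped at 0. The scan keeps SVs with pooled MAF > 0.01, sets the outlier
threshold at the empirical 99.9th percentile of the focal scores (strictly
"above" passes; NA scores excluded; `stats::quantile` type 7), and chains
above-threshold SVs within 1 Mb on a chromosome into independent signals.
IBS kinship is `mean((2 - |g_i - g_j|)/2)` over sites on 0/1/2 dosages,
and the genome-wide association threshold helper is `alpha / n_tests` to
two significant figures (0.05 / 29,510 tests gives 1.7e-6).

# Meta-chromosome density

Chromosome arms are rescaled to a common 0-2 coordinate (p-telomere to
centromere is 0-1, centromere to q-telomere is 1-2). Windows of 100 kb
slide in 50 kb steps along each arm; each window's count of SV midpoints
is placed at the normalized position of its center, and windows are
aggregated across chromosomes by averaging within 0.02-wide bins of the
normalized scale. Window width, step, the midpoint convention and the bin
width are all configurable — the source convention states "overlapping
windows" without a step, so 50 kb (half-window) is our default.

# The simulator: what it emulates, and what it does not

`simulate_genome()` builds chromosomes (default 3 x 10 Mb) with a central
centromere (10% of the chromosome), small gap and high-depth masks, and
non-overlapping protein-coding gene models (150 bp 5' UTR, 3-5 CDS exons
of 200 bp, 250 bp 3' UTR, strand-aware 1 kb promoter) placed clear of all
masks.

`simulate_population()` draws, per locus:

* **type** from the mix DEL 44.4%, INS 53.8%, DUP 1.4%, INV 0.4% — the
  per-sample composition reported for ONT cohorts;
* **length** from a four-component mixture — 55% lognormal body (median
  ~120 bp), 35% SINE-scale peak N(300, 30), 7% LINE-scale peak
  N(6000, 600), 3% long lognormal tail — reproducing the two
  characteristic indel length peaks near 300 bp and 6 kb. The peaks are
  reported quantities; the component *weights* are our calibration and are
  configurable. Lengths are clamped to [50 bp, 100 kb];
* **position** uniformly, outside all masks, with same-type truth loci
  kept disjoint (100 bp pad) so that each truth locus maps to one merge
  cluster. Loci are placed longest-first in length bands because a long
  locus only fits while the genome is sparsely occupied. All loci except
  planted pLoF deletions also avoid CDS intervals, which makes planted
  coding impact unambiguous (recovery must be exact, not approximate);
* **ancestral allele frequency** from Beta(0.3, 2) — singleton-heavy, like
  observed SV frequency spectra — truncated to at least one carrier by
  forcing a heterozygote into monomorphic draws; uniform and fixed-AF
  modes exist for calibration studies;
* **subpopulation frequencies** from the Balding-Nichols model,
  `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, and genotypes from
  Hardy-Weinberg sampling `Binomial(2, p_k)`.

Planted *differentiated* loci model local adaptation on the focal branch:
the focal subpopulation's frequency is displaced from the ancestral value
by the deterministic amount that sets the true focal-pair Hudson F_ST to
`diff_F` (shifting away from the nearer allele-frequency boundary), while
the other groups keep their neutral Balding-Nichols draws. A
Balding-Nichols *random* draw at high F would leave a large fraction of
"planted" loci barely differentiated — the per-locus divergence of a BN
draw is approximately chi-square(1)-shaped — which defeats the purpose of
planting known positives for a recovery test; the deterministic
displacement makes "planted" mean "differentiated".

`simulate_caller_calls()` emulates one caller: each carrier's SV is
emitted with the profile's per-type sensitivity; the start is jittered by
`round(N(0, sd))` and the length by a factor `1 + N(0, cv)`; site depth is
Poisson around the mean depth and supporting reads are binomial (p = 0.5
heterozygous, 1.0 homozygous). False positives arrive as Poisson(rate)
calls per sample at random positions kept clear of same-type truth loci by
more than twice the call's own length, so no false call can reach 50%
reciprocal overlap with truth. The default three-caller panel uses
sensitivities 0.95/0.90/0.85, jitter SD 10/20/30 bp, length CV 0.02 and
false-positive loads 300/500/800 per genome, mimicking the observed
disagreement between long-read callers. Everything is deterministic under
a fixed seed, including the emitted VCF bytes.

What the simulator does *not* model: sequence context (no reads, no
alignment, no basecalling error), repeat-driven breakpoint ambiguity
(jitter is homoscedastic Gaussian, while real callers err most inside
tandem repeats), caller-correlated errors (the three emulated callers err
independently, so the >= 2-caller consensus is more effective here than on
real data, where callers share failure modes), linkage disequilibrium
(loci are independent), and non-uniform SV placement (real SVs concentrate
in subtelomeric and repetitive regions; the simulated density profile is
flat by construction). Passing the pipeline-identity and operating-point
checks therefore demonstrates the correctness of the merging, filtering,
genotyping and scanning logic under the stated statistical conditions —
not caller performance on real genomes.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which the statistical criteria are meaningful: the operating-point
simulation uses 50 samples x 5,000 SVs on a 3 x 20 Mb genome at 15x (the
20 Mb chromosomes give same-type truth loci room to stay disjoint); the
PBS recovery uses 10 planted sweeps among 10,000 neutral loci with 100
samples in each of three groups, with a uniform(0.05, 0.95) ancestral SFS
so the MAF > 0.01 filter keeps essentially all loci and the 99.9% rank is
taken over the full set; F_ST calibration uses 10,000 neutral sites at
Balding-Nichols F = 0.05 with 100 samples per group; the CAST oracle
enumerates all partitions of 500 random groups of up to 6 intervals
(Bell(6) = 203 partitions each). Headline cohort-scale counts from
population studies (hundreds of thousands of nonredundant SVs) are not
reproducible at these sizes and are not asserted anywhere.

Other fixed choices: Hardy-Weinberg conformity of simulated genotypes is
checked with an exact conditional test (enumeration over heterozygote
counts), written in-package because no installed package provides one; its
conservatism below the nominal level is what makes a ">= 99% pass at
alpha = 0.01" check stable. The Bonferroni helper reports two significant
figures because that is how such thresholds are quoted. VCF support/depth
field mappings per caller dialect (Sniffles `RE` + `DV/DR`, NanoVar
`SR` + `DP`, NanoSV `DV/DR`) are our convention, documented in the
reader, since no common standard exists.

# Known limitations

* Sex chromosomes are treated as diploid throughout; genuine X/Y handling
  would need ploidy-aware AN accounting.
* The population merge genotypes non-carrying samples as 0/0, which
  conflates "confidently reference" with "not assayed"; a depth-aware
  no-call policy would be more conservative.
* CAST is a heuristic: on adversarial affinity patterns it can close a
  sub-optimal cluster (observed in under 5% of random small groups).
* The per-SV PBS scan has the power profile of single-locus statistics;
  window- or haplotype-based scans would detect weaker sweeps.
* Representative selection by modal `(start, svlen)` degenerates to the
  support/position tie-break under breakpoint jitter, which slightly
  biases representatives toward earlier coordinates for short SVs.
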