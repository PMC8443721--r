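---
title: "Heterozygosity landscapes and downstream analyses for clonal plant populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity landscapes and downstream analyses for clonal plant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalscape)
```

## The model

`clonalscape` analyses diploid SNP genotypes from populations that reproduce
largely asexually. Without recombination and segregation, heterozygosity is
not redistributed each generation; it is inherited wholesale. Two site
classes therefore dominate:

* **founder-heterozygous sites**: the clonal founder was heterozygous, so
  nearly all extant individuals are heterozygous there. Occasional losses
  (gene conversion, somatic homozygosis, genotyping error) leave a few
  homozygous calls.
* **somatic sites**: a mutation arose on one branch of the clonal genealogy
  and is carried, in heterozygous state, by exactly the samples descending
  from that branch — a small clade, hence a low carrier frequency.

The single-site statistic is the heterozygous-genotype frequency
$h = n_\mathrm{het} / n_\mathrm{called}$. Sites with $h \le 0.10$ are
labelled *low* (the somatic regime), sites with $h \ge 0.90$ *high* (the
founder regime); both boundaries are inclusive, reading "no more than 10 %"
and "no less than 90 %" literally. The window statistic is the unweighted
mean of $h$ over the SNP sites inside non-overlapping 200-kb tiles laid from
position 1 of each chromosome. With $m$ and $s$ the mean and (n−1) standard
deviation of the defined windows, windows above $m+s$ or below $m-s$ are
high- or low-heterozygosity windows, and maximal runs of them whose summed
span is strictly greater than 5 Mb are long continuous heterozygous regions
(LCHRs). The strict inequality matters: 25 windows of 200 kb (exactly 5 Mb)
do not qualify, 26 do.

Around this core the package implements the standard windowed
population-genetic statistics (θπ, θw, Tajima's D, Weir–Cockerham F_ST,
outgroup-polarized DAF), distance/network/Mantel analyses, a multi-method
GWAS consensus procedure, and the divergence-based mutation-rate formula
$\mu = D\,g / (2T)$.

## Conventions and tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| het window span | 200,000 | bp | heterozygosity window tiling |
| LCHR minimum run | 5,000,000 | bp | strict lower bound on run length |
| class boundaries | 0.10 / 0.90 | fraction | inclusive low/high limits |
| diversity window span | 100,000 | bp | θπ/θw/D/F_ST/DAF windows |
| MAF filter | > 0.05 | fraction | site kept iff strictly above |
| missingness filter | < 0.20 | fraction | site kept iff strictly below |
| LD pruning | 100 / 10 / 0.2 | SNPs / SNPs / r² | window, step, threshold |
| relatedness cutoff | 0.06 | IBS distance | greedy sample pruning |
| network fraction | 0.01 | fraction | lowest-quantile edges (0.005 preset also used) |
| Mantel permutations | 9,999 | — | one-sided, add-one p-value |
| GWAS top rank | 500 | — | consensus rule (b) |
| consensus methods | 2 | — | minimum methods for rule (b) |
| MTA merge gap | 10,000 | bp | single-linkage chaining |
| gene flank | 5,000 | bp | candidate-gene assignment |
| LOD threshold | 3 | — | suggestive cutoff for LOD tables |

Numerical conventions worth stating explicitly:

* **Windows** tile from position 1; the trailing partial window is kept with
  its true span (chromosome ends are not discarded) and its mean is computed
  normally. An SNP-free window is *undefined*: it is excluded from the
  mean/SD and it breaks an LCHR run, because "continuous" is read as
  contiguity of qualifying windows and SNP deserts should not bridge
  regions.
* **Mean/SD** for the thresholds use the sample (n−1) denominator; at
  genome scale (hundreds of windows) the difference from the population
  denominator is far below the printed precision.
* **θπ** uses the fixed window span as denominator (the windowed-π
  convention of the common VCF tools), not the number of callable sites.
  With per-site allele counts $c_\mathrm{ref}, c_\mathrm{alt}$ and
  $k = c_\mathrm{ref} + c_\mathrm{alt}$ called alleles,
  $\pi_\mathrm{site} = 2 c_\mathrm{ref} c_\mathrm{alt} / (k(k-1))$.
* **θw** sums $1/a_1(k_\mathrm{site})$ over segregating sites so that sites
  with missing genotypes (smaller $k$) use their own harmonic constant.
* **Tajima's D** needs one $k$ per window for its constants; the per-window
  mode of the called-allele count is used. Windows with $S = 0$ or $k < 4$
  are flagged undefined rather than set to zero, so empty windows cannot
  masquerade as neutral ones.
* **F_ST** is Weir & Cockerham (1984): per-site components a, b, c and the
  ratio-of-sums $\sum a / \sum(a+b+c)$ within windows. A window with no
  usable polymorphic site is undefined.
* **DAF**: a site is polarizable only if the outgroup genotype is called and
  homozygous; that allele is ancestral. A heterozygous or missing outgroup
  call excludes the site rather than guessing.
* **Top-quantile calling**: the cutoff is the $\lceil f n\rceil$-th largest
  window value and ties at the cutoff qualify. This, not the type-1
  $(1-f)$ quantile, makes "top 1 % of 100 windows" select exactly one
  window when $fn$ is an integer.
* **IBS/Hamming distances** use the flat-missing convention: a pair–site
  with any missing call contributes zero mismatches while the denominator
  stays $2 \times$ total sites. Hamming is the same tally unnormalized.
* **LD pruning** works on genotype-dosage r² (composite LD). True phase is
  unavailable in unphased data, so the phased-pair variant of the pruning
  command is approximated by dosage correlation — a documented deviation.
* **Greedy pruning tie-breaks**: in sample pruning, the member of the
  closest pair with more sub-cutoff neighbours is dropped, ties toward the
  lexicographically larger id; in LD pruning, the SNP in the most offending
  pairs, ties toward the later position. Both are deterministic.
* **Mantel test**: $x = F_{ST}/(1-F_{ST})$ linearizes differentiation for
  distance regression; the permutation p-value uses the add-one rule
  $(1 + \#\{r_\pi \ge r_\mathrm{obs}\})/(1 + n_\pi)$ and can never be 0.
* **Consensus rule**: "identified by more than two methods" is read as "at
  least two" (`min_methods = 2`), the common idiom in translated methods
  text; the literal reading is one flag away (`min_methods = 3`).
* **Bonferroni m**: the effective SNP number is an input (it comes from an
  external estimator); when absent, the raw SNP count is the conservative
  default.

## What the simulator emulates

`simulate_population()` draws three independent Poisson position streams per
chromosome and assembles one genotype matrix:

* **founder sites** (default density 1.7 × 10⁻⁴/bp): each ingroup sample is
  heterozygous with probability 0.96, otherwise homozygous for either allele
  with equal probability — so ~99 % of founder sites have carrier frequency
  ≥ 0.90 at n = 100.
* **somatic sites** (default rate 2.3 × 10⁻⁶ per lineage per bp, total
  scaling with sample number): a random bifurcating clonal genealogy
  (`ape::rtree`) is drawn once; each somatic site picks one edge whose clade
  holds at most 10 % of samples, and exactly that clade is heterozygous.
  When missingness is enabled the cap is one sample stricter, so carrier
  frequencies *over called genotypes* stay at or below the 10 % boundary
  even when a non-carrier call is masked.
* **background sites** (default density 1 × 10⁻⁴/bp): ordinary standing
  variants in Hardy–Weinberg proportions within groups. Group frequencies
  are $p_g = p + \sqrt{F\,p(1-p)}\, z_g$ with an ancestral
  $p \sim U(0.1, 0.9)$ — the same first two moments as Balding–Nichols
  draws at inbreeding coefficient $F$, so the expected Weir–Cockerham F_ST
  matches `group_fst_target`. The $z_g$ are standard normals correlated as
  $\exp(-d_{gh}/\mathrm{range})$ over the great-circle distance between
  group centres (standardized so the mean pairwise variance matches
  independent draws), which yields isolation by distance: nearby groups are
  more similar. A Gaussian perturbation replaces the Beta draw because the
  targets of interest are tiny (10⁻⁴–10⁻³, up to 0.05 in tests) and the
  spatial correlation is awkward to impose on Beta margins; at these F
  values the two are indistinguishable in the moments that F_ST estimators
  see.

The default densities put roughly 46 % of sites in the somatic (low) class,
35 % in the founder (high) class and 19 % in between — the regime of a
heavily clonal, low-diversity population. Planted high/low-LCHR intervals
(two 6-Mb regions of each class on an 80-Mb two-chromosome genome, aligned
to the 200-kb grid) multiply the founder rate by 6 and the somatic rate by
4 inside high and low regions respectively (and suppress the opposite
class), so the window track crosses the mean ± SD thresholds inside and only
inside the planted regions. One outgroup sample (`OG1`) is appended when
enabled: homozygous at ≥ 99 % of sites (90 % reference, ~9.5 % alternate),
providing both polarities for DAF tests. Missingness is uniform at random
(default 2 %), independent of genotype — the simplest null for filter
testing. Monomorphic sites are dropped.

Phenotypes are nine traits: each causal SNP (drawn from background sites
with allele frequency in [0.2, 0.8]) adds `effect_size` × true dosage to its
assigned trait; all traits share `env_weight` (default 0.3) times the
leading latent environmental factor; residual noise is Gaussian with SD 1,
so effects are in phenotype-SD units. The 12 environmental factors are
latitude, longitude and ten derived variables generated from
`env_latent_dim` latent factors (the first two follow latitude and
longitude) with loading noise, in standardized units. Annotation is a
10-kb-pitch gene tiling (3-kb genes, jittered within slots) with 1–5 terms
per gene drawn with Zipf popularity weights, giving heavy-tailed term sizes.

**What the simulator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium within the background
class (sites are independent), mutation-rate heterogeneity along the genome
beyond the planted regions, genotyping error correlated with depth or
heterozygosity, gene conversion tracts, cryptic relatedness beyond the
clonal genealogy, selection, and any sequence-level artefacts (the
generator emits genotypes, not reads). Recovery results on this generator
demonstrate the *procedures* are implemented correctly and calibrated under
their stated assumptions, not that those assumptions hold in any particular
organism.

## Problem sizes used by the tests and the acceptance script

The package's own verification uses desk-scale instances chosen to make
sampling error small relative to the tolerances: oracle-equivalence checks
on ≤ 20-sample, ≤ 1,000-site matrices at 10⁻¹⁰ relative tolerance;
class-fraction and LCHR recovery on the default 80-Mb, ~54,000-site
simulation; F_ST target recovery (0.05 ± 0.02) on 60 samples in two groups
at ~20,000 sites; causal-SNP MTA + gene recovery on 20 independent
simulations of 190 samples × ~5,000 SNPs with a single 0.8-SD causal SNP;
and calibration of the batch chi-square (20,000 null sites) and Mantel test
(1,000 null replicates, 99 permutations each, so the discrete null
rejection probability at α = 0.05 is exactly 0.05).

## Known limitations

* `window_fst` assumes the Weir–Cockerham estimator is meaningful for the
  supplied grouping; with near-clonal samples inside groups the
  within-group heterozygosity term dominates and per-site estimates are
  noisy — the windowed ratio-of-sums is the quantity to interpret.
* `associate_linear` is ordinary least squares with covariates. It is the
  package's stand-in association generator for exercising the consensus
  machinery; it does not model kinship, and result tables from mixed-model
  or multi-locus methods should be supplied via `association_table` for
  real analyses.
* The LD pruner guarantees no offending pair *within a scan window*;
  distant pairs on the same chromosome are not examined, matching the
  windowed semantics of the standard tool.
* `read_vcf` handles biallelic SNP GT fields; genotype likelihoods, phased
  haplotype analysis and multiallelic decomposition are out of scope.
* Jaccard recovery of planted LCHRs is window-quantized: planted intervals
  not aligned to the window grid lose up to one window of overlap per edge.
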