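---
title: "Methods: imputation QC, ROH and IBD for low-coverage ancient genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputation QC, ROH and IBD for low-coverage ancient genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Most ancient genomes are sequenced far below the coverage needed for
confident diploid genotype calls, so analyses fall back on pseudohaploid
data — one randomly sampled allele per site — and lose access to
heterozygosity-based inference. Genotype imputation against a large modern
reference panel can recover diploid genotypes from sub-1x data, but only if
its error structure is understood and controlled. `paleoimpute` implements
the post-imputation analysis stack for this setting: accuracy metrics
stratified by the variables that drive imputation error, genome scans for
systematically misimputed regions, two runs-of-homozygosity (ROH) callers
and their fusion, identity-by-descent (IBD) post-processing into a binary
relatedness classification, and an outgroup f3 statistic with a block
jackknife. A synthetic-data generator supplies inputs with the statistical
structure these methods assume, so every claim the package makes is
testable without restricted data.

# Accuracy metrics

All metrics compare a truth callset (high-coverage genotypes) with an
imputed callset on a shared site list, after an optional genotype
probability (GP) filter. With confusion counts `n[t -> i]` of truth dosage
t against imputed dosage i:

* **Non-reference concordance** = `(n[1->1] + n[2->2]) / n[t in {1,2}, i in
  {0,1,2}]`. Homozygous-reference truth sites are excluded because they are
  easy to impute and would inflate the rate; the denominator is conditional
  on a call being made (imputed-missing sites after GP filtering are
  excluded). An `conditional = FALSE` flag reports the unconditional
  variant. The conditional reading matches computing concordance "over
  matching sites" between a validation set and a GP-filtered callset.
* **Heterozygous FPR** = `FP / (FP + TN)` with `FP = n[0->1] + n[2->1]` and
  `TN = n[0->0] + n[2->2]`. Note that TN requires the imputed homozygote to
  equal the truth homozygote; a cross-homozygote error (`0->2`, `2->0`)
  counts in neither term. This follows the letter of the defining formula
  ("correctly imputed homozygous sites").
* **Heterozygous FNR** = `(n[1->0] + n[1->2])` over truth heterozygotes
  with a non-missing imputed call.

Undefined rates (empty denominators) propagate as `NA`, never silently as
0. Stratification is by panel minor-allele-frequency tranche — (0,1],
(1,2], (2,5], (5,10], (10,20], (20,50] percent, left-open/right-closed, so
a MAF of exactly 5% falls in (2,5] — and by substitution class (transition
vs transversion, the class confounded by postmortem deamination). MAF
always means the *panel* frequency; sample frequencies are never used for
stratification. The GP filter keeps a call iff `max(GP) >= threshold` and
the recorded genotype equals the GP argmax (an imputation model emits the
argmax, so a mismatch marks a corrupt record); the conventional threshold
ladder is 0.7, 0.8, 0.9, 0.95, 0.99.

# Windowed genome scans

`make_windows()` produces 500 kb windows at a 100 kb step (the
bedtools-makewindows dialect: starts at every multiple of the step below
the chromosome length, final windows truncated). Per-window concordance or
FPR uses every window containing a site. Outlier regions are the bottom
(concordance) or top (FPR) 1st percentile of windows with a *defined*
rate; windows with no compared sites are excluded from ranking rather than
scored zero, so coverage deserts are not called outliers. The percentile
is nearest-rank (ceiling); ties at the threshold are all selected and
flagged, since the quantile definition is otherwise arbitrary. Selected
windows that overlap or touch merge into regions; regions recurring in at
least three samples are reported as systematic. A convenience flag
annotates (but does not auto-drop) regions near chromosome ends, where
assembly artifacts concentrate.

# ROH calling

Two callers with opposing biases are fused:

* **Window scan** (`windowscan_roh()`): the plink-style algorithm with the
  parameterization used for imputed ancient data — 50-SNP windows, at most
  1 heterozygote and 5 missing calls per hit window, 5% hit-fraction SNP
  threshold, and final filters of >= 200 SNPs, >= 500 kb, <= 50 kb/SNP,
  gaps <= 100 kb. The reference implementation's end-extension rules are
  undocumented, so this package fixes one oracle-testable choice: candidate
  runs are trimmed so both ends are non-missing homozygous calls. No cap is
  placed on heterozygotes inside a final run (the windows provide that
  control). The caller is verified against an independent brute-force
  implementation on a thousand random instances.
* **HMM** (`hmm_roh()`): a two-state (autozygous/Hardy–Weinberg) HMM over
  called genotypes in the style of genotype-based autozygosity HMMs, with
  phred-scaled genotype error `-G 30` (e = 0.001), default allele frequency
  0.4 where the panel frequency is unknown, and distance-scaled transition
  probabilities capped at 0.49 (defaults 6.7e-8/bp into autozygosity,
  5e-9/bp out — the referenced tool's standard values; the source analysis
  set only the error and default-AF parameters). The initial state
  distribution is uniform; missing genotypes are dropped before the HMM.
  Viterbi AZ runs are reported with a quality score `-10 log10(1 - median
  per-site AZ posterior)` from forward–backward; any monotone posterior
  summary satisfies the quality>10 filter semantics and the median is
  robust to single-site dips. Filters: >= 200 SNPs, quality > 10, >= 500
  kb. Viterbi is verified against exhaustive path enumeration for up to 12
  sites.
* **Fusion** (`fuse_roh()`): the window scan under-calls long ROH at low
  SNP density, while the HMM recovers long ROH well but over-calls short
  stretches. The fusion keeps HMM segments strictly longer than 4 Mb,
  merges them into the full window-scan profile (touching intervals merge),
  and records the mergeBed-style count and collapsed lengths of the inputs.
  Thresholds follow the stated wording: "> 4 Mb" strict, ">= 200 SNPs" and
  ">= 500 kb" inclusive.

Length-bin summaries use edges 0.5, 1, 2, 4, 8 Mb and infinity; bins
partition the total by construction. `downsample_sites()` thins a callset
to a fixed number of called sites to match SNP density across samples and
to study density-driven ROH fragmentation.

Group contrasts of cumulative ROH use an exact one-tailed Mann–Whitney U
test (`mwu_groups()`): U counts directional pairs, and the p-value is the
lower tail of the exact null distribution computed by dynamic programming
on the Gaussian binomial coefficient (partition counting), which is exact
integer arithmetic. Cross-group ties are refused rather than approximated:
cumulative-Mb inputs are effectively continuous, and a tie would
invalidate the exact distribution.

# IBD post-processing and relatedness

Segment tables from repeated detection runs are pooled per sample pair:
records below LOD 3 are dropped, excluded regions are excised first (by
default the first 2 Mb of chromosome 18, an extreme apparent-recombination
region attributed to an assembly error), segments are unioned per pair and
chromosome, and merged segments shorter than 3 cM are removed. Consecutive
segments with gaps strictly below 0.6 cM then merge transitively (a strict
threshold guarded against interpolation round-off by a 1e-9 epsilon). The
main-analysis convention consumes IBD1 segments without wider merging; a
validation mode against duplicate genotypes would merge within 4 cM — the
gap parameter exposes this as configuration. A pair is **related** when it
shares at least 3 segments each strictly longer than 3 cM whose cumulative
length is at least 21 cM; the cumulative total is computed over the
qualifying segments only, reading the phrase as binding the total to the
three-segment clause. The merge criterion used by haplotype-based tools of
"at most one discordant homozygote" needs genotype access inside gaps and
cannot be evaluated from segment tables; gap-distance merging alone is
applied.

**Normalized relatedness** of a group (minimum three samples) is the
fraction of individuals with at least one related partner inside the
group. This individual-level definition is chosen because published values
are glossed as "all of the tested individuals were related" (value 1) and
"roughly half of the individuals" (0.55); a pair-fraction variant is
available via `level = "pair"`. Between-group sharing is the symmetric
matrix of cumulative merged cM over cross-group pairs.

# Outgroup f3

`outgroup_f3()` estimates shared drift of A and B relative to outgroup O
as the mean over usable sites of `(o - a)(o - b)` on ALT-allele
frequencies; sites missing in any population are skipped. No finite-sample
bias correction is applied (the outgroup-mode convention; a correction
flag is a documented extension). Standard errors use a delete-one-block
jackknife over contiguous 5 Mb physical blocks, weighted by block site
counts (`h_j = N/n_j` pseudovalue weights); the block scheme is a default
because the upstream tooling does not expose its own. The leave-one-block
estimates are returned so the jackknife can be audited against direct
recomputation, which the test suite does.

# The synthetic-data generator

The generator produces data with the properties the analyses rely on, not
a forward population-genetic simulation:

* **Panel** (`simulate_panel()`): founder haplotypes drawn per site from
  Bernoulli(p), p ~ Beta(0.3, 0.3) — a U-shaped law giving the excess of
  rare alleles of an empirical site-frequency spectrum — and non-founder
  haplotypes built as recombinant mosaics of the founders, switching donor
  with probability 0.05 per cM. Mosaic copying provides LD and a realistic
  MAF spectrum with two parameters; a coalescent backend could be swapped
  in but is not required. Defaults are a desk-scale stand-in for a
  livestock panel: 2 chromosomes x 50 Mb at 1 cM/Mb, 50,000 sites each,
  100 haplotypes from 20 founders.
* **Truth** (`simulate_truth()`): individuals are two panel mosaics.
  Planted ROH overwrite the second haplotype with the first (exact
  homozygosity); planted IBD copy one donor haplotype into both pair
  members. Because mosaic individuals also carry *chance* autozygosity,
  a planted tract can abut a natural homozygous run; recovery is therefore
  always measured against the realized autozygous tract (the planted
  coordinates extended to the containing homozygous run), which is the
  only boundary a genotype-level caller can identify.
* **Imputed** (`simulate_imputed()`): a call is wrong with probability
  `p_wrong[tranche, class] * exp(-k * coverage)` — rarer alleles and
  heterozygotes impute worse, accuracy rises with coverage (k = 1 by
  default). Wrong heterozygotes become the major-allele homozygote; wrong
  homozygotes become heterozygous 80% of the time, making spurious
  heterozygotes the dominant error mode, as observed in practice. Max-GP is
  drawn from Beta(8, 0.4) for correct and Beta(2, 2) for wrong calls,
  mapped into (0.5, 1) as `0.5 + B/2` so the GP argmax always equals the
  emitted genotype (the remaining mass is split 9:1 between the runner-up
  and the third class; only max-GP matters downstream). These Beta laws
  are calibration devices, not estimates of any imputation model's
  empirical GP distribution.
* **Pseudohaploid** (`pseudohaploidize()`): per-site depth ~
  Poisson(coverage); zero depth is missing, otherwise one allele sampled
  uniformly from the diploid genotype. Missingness is exactly
  `exp(-coverage)` in expectation.
* **IBD tables** (`emit_ibd_tables()`): each planted tract is emitted per
  run with cM-space boundary jitter (±0.2 cM), optionally split by a gap
  below 0.6 cM, plus decoy negatives (segments under 3 cM, and low-LOD
  segments under LOD 3) between unplanted pairs.

The generator's core contract, enforced by tests, is calibration:
measured per-stratum concordance matches `1 - effective error` within
three binomial standard deviations, and concordance restricted to calls
passing a GP threshold is non-decreasing in the threshold.

What the generator does **not** emulate: postmortem deamination profiles
(the motivating analyses found little systematic error difference at CpG
sites after transversion-aware filtering), reference-panel phasing error,
read-level artifacts, and real demographic history. Passing tests
therefore demonstrate that the *analysis stack* is correct and calibrated,
not that any particular imputation model achieves these error rates on
real ancient DNA.

# Numerical choices and problem sizes

Reproducibility: every generator takes an explicit seed and restores the
caller's RNG state; equal seeds give byte-identical outputs. Internal
coordinates are 0-based half-open everywhere; VCF positions are converted
at the boundary and BED passes through unchanged. Genotypes are diploid
unphased; phase separators are accepted on read and emitted as `/`.

The test suite and the acceptance script run at desk scale, chosen so that
statistical checks have the power their tolerances assume: accuracy
calibration uses 100,000 sites (where a 1.5% rate has a binomial SD of
about 0.04 percentage points), trend checks compare only strata with at
least 2,000 denominator sites (binomial SD < 0.25 percentage points,
inside the 0.005 trend tolerance), ROH recovery uses 25,000 sites over 50
Mb (one site per 2 kb, comfortably above the one-per-3-kb density at which
recovery is expected), and oracle-equivalence checks run 1,000 window-scan
instances and 500 HMM parameterizations. Planted IBD tracts for the
relatedness recovery checks are 8 cM each, three per pair: tracts at
exactly the 5 cM qualifying floor would sum to 15 cM and could never meet
the 21 cM cumulative rule, so planted *related* pairs must carry tracts
above 7 cM.

# Known limitations

* The window-scan trimming rule is one defensible reading of an
  undocumented reference behavior; segment boundaries may differ from the
  reference tool by a few SNPs at run ends.
* The HMM quality score is a posterior summary, not the reference tool's
  internal score; only its filtering semantics (monotone, thresholded at
  10) are preserved.
* Relatedness is a binary eighth-degree-style rule, not a kinship-degree
  estimator.
* f3 is implemented in outgroup mode without the finite-sample
  h-correction; within-population drift of the outgroup cancels only in
  comparisons sharing the outgroup.
* Multiallelic sites, indels and sex chromosomes are out of scope
  (autosomal biallelic SNPs only).
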