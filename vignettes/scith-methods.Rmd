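---
title: "Methods: single-cell and multi-region intratumor heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell and multi-region intratumor heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scith)
```

## The problem

A solid tumor is a mosaic of genetically related cell populations. Bulk
sequencing of a biopsy reports the average genome of that mosaic, so two
complementary designs are used to resolve intratumor heterogeneity (ITH):
multi-region whole-exome sequencing (several spatially separated pieces of
one tumor, each a different clone mixture) and single-cell whole-genome
sequencing (tens of amplified single cells at shallow depth). `scith`
implements the analysis layer for this design: binned copy-number
profiling of amplified single cells, quality control, consensus building,
a dual-caller somatic mutation catalog with regional categorization,
rule-based classification of sorted cells into tumor/normal/mixture, and
detection of *subclonal* copy-number alterations that split the tumor-cell
population into subpopulations. Every stage can be exercised on synthetic
data with known ground truth, which is how the test suite validates it.

## Copy-number profiling of shallow single-cell data

Read counts are aggregated in a fixed tiling of ~500 kb bins (0-based,
half-open; the last bin of a chromosome may be short). For a cell with
per-bin counts $r_b$ and a matched-control (blood) count vector $c_b$, the
depth ratio is

$$\rho_b = \frac{r_b / \sum_b r_b}{c_b / \sum_b c_b},$$

rescaled so the median autosomal $\rho_b$ is 1 (diploid baseline). The
control cancels mappability and GC structure shared between sample and
control; bins with inadequate control coverage are masked and later
imputed from the nearest decoded bin (display only — masked bins are
excluded from MAPD and clustering).

**MAPD.** Whole-genome-amplified single cells have strongly overdispersed
depth. The per-cell quality score is the median absolute difference of
*consecutive* bin log2 ratios within chromosomes,
$\mathrm{median}_i\,|l_{i+1}-l_i|$. For iid Gaussian noise of sd $\sigma$
this equals $\sigma\sqrt{2}\,\Phi^{-1}(0.75)$, which the tests verify by
Monte Carlo. Consecutive differences measure bin-to-bin technical noise
while being insensitive to genuine long-range copy-number structure; a
literal all-pairs median would instead measure profile variance, so the
consecutive-bin convention (the standard one for this metric) is used.
Cells pass QC iff MAPD $< 0.25$ (strict).

**Integer copy number.** States $s \in \{0,\dots,8\}$ are decoded by
Viterbi over each chromosome with Gaussian emissions centered at $s/2$ on
the ratio scale and a shared emission sd, by default estimated robustly
from consecutive-bin differences (`mad(diff(ratio))/sqrt(2)`), i.e. from
within-segment noise. Transitions keep the current state with probability
0.995 and spread the rest uniformly; this smooths isolated outlier bins
while multi-bin events survive. Both the stay probability and the emission
sd are exposed (`pipeline_params()`); fixing `hmm_emission_sd` makes the
degenerate limits exactly reproducible (stay probability near 0 with small
sd reduces decoding to per-bin rounding of $2\rho_b$, which the tests
assert). State 0 is given a small positive emission mean (0.05) so the
zero state does not collapse.

**Consensus and similarity.** A clone's profile is summarized as the
per-bin median integer state across its cells (even counts take the lower
middle value, keeping the consensus integral). Profile similarity is
pairwise Pearson correlation over mutually unmasked bins.

## Mutation catalog

Two independent callers' per-region tables are intersected: an SNV is a
*consensus* call in a region iff both callers report it there. Retained
variants then pass three filters: base quality $\ge 30$; a spacing rule
that removes **both** members of any same-chromosome pair closer than
15 bp (the symmetric reading — conservative, since which member is the
artifact is unknowable at this stage); and mandatory germline subtraction
by exact (chrom, pos, ref, alt) match against the matched-blood calls.
Allele-aware matching was chosen over position-only because the blood
table in this design comes from the same caller and coordinate system.

**Low-VAF rescue.** A variant that is a consensus call in at least one
region of a patient regains presence in any other region where exactly
one caller saw it, provided the observed VAF there exceeds 0.2 (strict).
Eligibility is anchored on a same-patient consensus call because the
rule's purpose is recovering false negatives of variants whose reality is
already established; un-anchored rescue would re-admit single-caller
artifacts. Indels from the designated single caller are then unioned in
(deduplicating on the variant key, keeping the max-quality record), and
each variant is categorized from its post-rescue regional presence:
**ubiquitous** (all regions), **shared** ($\ge 2$ but not all),
**private** (exactly one). With a single region everything is degenerately
ubiquitous; this is documented rather than hidden.

Mutation spectra count SNVs per region over the six pyrimidine-collapsed
substitution classes (C>A, C>G, C>T, T>A, T>C, T>G). Group differences use
a chi-squared test on the full table or a two-sided Fisher exact test on a
2x2 collapse (focal class vs rest, focal group vs rest). No multiple
testing correction is applied, matching the analysis this package models.

## Cell identity

Sorted "tumor" cells still contain somatic diploid cells and occasional
cell-plus-debris mixtures. Each cell is classified from two inputs: a
copy-number flag (`ploidy_flag`: any contiguous autosomal run of
non-diploid bins spanning $\ge$ 5 Mb; the span default suppresses isolated
HMM errors and is configurable) and targeted validation-assay outcomes on
two panels — 5–6 ubiquitous nonsynonymous mutations (diploid screen) and
14 nonsynonymous mutations (tumor confirmation):

* no SCNA, zero candidate mutations &rarr; **normal** diploid;
* no SCNA, more than 3 candidate mutations &rarr; **mixture** (excluded);
* SCNA present, $\ge 4$ of 14 tumor-panel mutations &rarr; **tumor**;
* anything else &rarr; **ambiguous** (excluded downstream).

Failed assays count as absent, which is conservative toward exclusion:
a cell never becomes tumor or mixture on the strength of a failed
reaction. Diploid cells with 1–3 validated mutations are ambiguous rather
than normal or mixture — the source procedure detailed only the
"more than three" exclusion, so the gap is closed on the cautious side.

## Subclonal SCNA detection

Tumor-cell integer profiles form a cells x bins matrix. Bin mining
proceeds in nested stages (each a subset of the previous, which the tests
assert): drop bins that are zero everywhere or nonzero in fewer than 3
cells; keep bins with across-cell variance $> 0.5$ (for an integer CN
change of 2 this admits subclone fractions between roughly 0.15 and 0.85);
run centered, unscaled PCA on the retained matrix and collect, on each of
PC1–PC6, bins whose squared-loading contribution is at least the average
contribution $1/n$; take the union. Unit scaling is deliberately omitted:
the variance filter has already equalized the scale regime, and scaling
would inflate marginal bins. The contribution criterion is the standard
"above average" rule of PCA contribution analysis; a top-quartile rule was
considered and rejected because with a small retained-bin set it caps
recall by construction (at most a quarter of bins per component), failing
recovery on clean planted events. The multiplier is a config knob
(`contribution_multiplier`).

Candidate bins are grouped into maximal runs of genomically adjacent bins
(one missing bin tolerated inside a run, no crossing of chromosome
boundaries) and runs spanning $\ge$ 1.5 Mb (inclusive) are kept. This
automates what was originally a manual selection step, trading judgment
for reproducibility. Cells are then clustered on the selected bins:
Ward.D linkage on Euclidean distances for the dendrogram, and PAM at each
$k$ in 2..10 with the largest average silhouette width choosing $k$
(the `pamk` selection rule, implemented on `cluster::pam`). Subpopulation
frequencies are cluster sizes over the total, reported as integer-rounded
percent (6 and 29 cells of 35 give 17% and 83%) with exact fractions
retained.

## The synthetic world

The generator (`sim_config()`, `simulate_dataset()`) states the world the
tests run in; its defaults are the modeled study design where stated and
a single realistic choice where not:

* **Design**: 4 regions, 10 sorted cells per region, ~500 kb bins on an
  hg19-like genome (autosomes + X); a three-clone tree (root, a subclone
  confined to regions B–D, a sub-subclone confined to D) so the catalog
  has ubiquitous/shared/private structure; clonal chr20q gain, chr18q
  loss, chr8q gain and a multi-Mb subclonal event, echoing the common
  colorectal pattern.
* **Depth**: `depth_mean = 60` reads per bin for single cells — a free
  parameter standing in for ~0.3x coverage (0.3 x 500 kb / 150 bp paired
  reads is a few tens of read pairs per bin); bulk regions at 500.
* **Noise**: per-bin negative binomial, overdispersion calibrated by the
  delta method so realized log2-ratio MAPD matches `target_mapd`
  (default 0.20, below the 0.25 QC cut): the required count-scale variance
  at the diploid mean is $(\sigma \ln 2\, \mu)^2$ with
  $\sigma = \mathrm{MAPD}/(\sqrt{2}\,\Phi^{-1}(0.75))$; targets below the
  Poisson floor fall back to Poisson. A smooth cell-specific lognormal
  wave (sd 0.05, period ~1/30 of the genome) mimics amplification
  nonuniformity without inflating consecutive-bin differences.
* **Purity**: 50% diploid contamination per region (the modeled tumors
  ranged roughly 25–50% purity by WES); 30% of sorted cells are diploid
  (the observed 15/40 and 13/48).
* **Mutations**: per-region true VAF = carrier-clone fraction x 0.5 x
  purity plus small Gaussian noise; each caller independently misses a
  true (variant, region) with `caller_fn_rate` (default 0.05); planted
  germline variants (VAF ~0.5 everywhere and in blood) exercise
  subtraction; single-caller indels exercise merging. Validation assays
  flip present to absent with `ado_rate` (default 0.2, the regime in
  which ubiquitous mutations are "sporadically identified" in single
  cells) and fail outright with `assay_fail_rate` 0.05.
* **Seeds**: one master seed; each stage draws from a derived child
  stream, so partial reruns reproduce.

What the generator does **not** emulate: read-level artifacts (chimeras,
sequencing error), GC/mappability bias (the control is an expectation, not
a noisy library), doublet depth physics, spatially correlated allelic
dropout, and caller-specific error profiles beyond a uniform miss rate. A
green test therefore establishes that the *rules and estimators* are
implemented correctly and recover a stated stochastic world — not that
the pipeline is robust to every artifact of real MALBAC libraries.

## Numerical choices and degenerate inputs

* Event-to-bin assignment during simulation: a bin takes an event's copy
  number when the event covers at least half the bin (symmetric,
  unambiguous).
* Median ties in consensus profiles: lower middle value (integer result).
* Constant profiles have undefined Pearson correlation: masked with a
  warning rather than silently zeroed.
* `pam_choose_k` on $\le 2$ cells returns $k = 1$ with a warning; a weak
  best silhouette (< 0.25) sets a low-confidence flag instead of failing.
* Empty selected-bin sets propagate as a single-subclone result with a
  warning, never an error, so null tumors flow through the pipeline.
* All rule thresholds are strict exactly as stated: quality `< 30`
  dropped, spacing `< 15` dropped, rescue `> 0.2`, MAPD `< 0.25` passes,
  tumor `>= 4`, mixture `> 3`.

## Known limitations

Allele-specific copy number, purity/ploidy joint estimation, phylogenetic
tree inference and cancer-cell-fraction modeling are out of scope. The
acceptance suite runs the recovery simulations on a 3 x 60 Mb genome to
stay within test budgets; the statistical regime (MAPD, depth, subclone
fraction, event sizes) is unchanged from the stated world, but absolute
bin counts are config-dependent and never asserted.
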