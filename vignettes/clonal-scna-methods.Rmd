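---
title: "Methods: clonality of copy-number alterations and drug-response association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality of copy-number alterations and drug-response association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalSCNA)
```

# Scope

`clonalSCNA` implements the computational core of a multi-region tumour
copy-number analysis for chromosomally unstable cancers such as high-grade
serous ovarian carcinoma (HGSOC): classifying somatic copy number
alterations (SCNAs) as clonal or subclonal from allele-specific
copy-number profiles of several regions per patient, summarising
gene-level copy number into categorical states and cohort frequency
profiles, estimating drug-response AUC and IC50 from viability plates
with a robust outlier screen and spline fit, and the resampling
statistics that connect clonal driver copy number to drug response.
Because the patient-level data this kind of study uses are
access-restricted, every analysis here is exercised on synthetic data
with known ground truth; the generators are first-class, tested code.

# Clonality of SCNAs

## Model

Each tumour region is described by allele-specific segments (raw minor
and major copy number) plus a sample ploidy. The non-allele-specific raw
total copy number of a segment is

$$\mathrm{rawtotalCN} = \log_2\!\frac{\mathrm{raw\ minor} + \mathrm{raw\ major}}{\mathrm{ploidy}},$$

computed per segment. A segment is a **gain** when
$\mathrm{rawtotalCN} > \log_2(2.5/2)$ and a **loss** when
$\mathrm{rawtotalCN} < \log_2(1.5/2)$; the inequalities are strict, so a
value exactly at a threshold is neutral. A total raw copy number of zero
maps to the sentinel $-\infty$, documented as homozygous null and
treated as loss. Loss of heterozygosity (LOH) is called when the raw
minor copy number falls below a threshold, default 0.25 — the midpoint
that separates a true minor copy number of 0 from 0.5 under symmetric
noise; the threshold is configurable.

Per patient, a **consensus profile** is built by intersection
segmentation: the consensus breakpoints are the union of all regions'
breakpoints, mask intervals (low-mappability or otherwise inaccessible
regions, supplied as BED) are removed, and every consensus segment
carries one raw total copy number and one LOH flag per region.
Per-region values are carried rather than averaged because clonality
needs per-region states. A gain is **clonal** when every region of the
patient classifies the consensus segment as gain, **subclonal** when at
least one but not all do. Loss is analogous, with a region counting as
lost when it either classifies as loss relative to ploidy or carries
LOH. Gain and loss labels are independent fields: with several regions,
some may gain while others lose the same locus.

## Design choices

* Clonality is called at consensus-segment resolution and aggregated to
  genes or bins by interval overlap; contiguous same-label segments are
  not merged into larger "events", since any merging rule would be
  arbitrary at this resolution.
* Whether a clonal call requires identical event boundaries across
  regions or merely overlap is undefined at segment resolution; the
  consensus segmentation sidesteps the question because every region
  contributes a state to every consensus segment.
* Coordinates are 0-based half-open throughout (BED-compatible).
* Single-region patients cannot carry subclonal labels; calls are
  restricted to clonal/none with a warning.
* In the cohort frequency track a patient contributes at most one
  category per direction and bin (clonal takes precedence over
  subclonal), so clonal% + subclonal% never exceeds 100%. Percentages
  are relative to the patients with consensus coverage in the bin; a
  bin covered by no patient is reported missing, not zero.

# Gene-level copy number

Absolute (ploidy-adjusted) copy number (ACN) is categorised with
boundaries 0.5 / 1.5 / 2.5 / 4.5, half-open on the left: homozygous
loss, heterozygous loss, neutral, gain, amplification. This matches the
integer convention that 3 or 4 copies are a gain and 5 or more an
amplification. The 3-level view used by trend tests collapses integer
ACN to "2" (&le; 2), "3" and "4+". Gene-level summarisation from
segments takes the segment with the largest overlap, breaking ties
toward the higher copy number so focal amplifications are not missed.
Relative copy number (RCN, log2-ratio scale) converts to ACN as
$\mathrm{ACN} = \mathrm{ploidy}\cdot 2^{\mathrm{RCN}}$, with ploidy 2
assumed when unknown. Missing values are excluded from denominators and
never imputed.

The marker-stratified frequency difference (e.g. MYC) compares
alteration frequencies between marker gain/amplification samples and a
comparison group. Whether marker-loss samples belong in the comparison
group is genuinely open; the default compares against marker-neutral
samples only, and `comparison = "non_altered"` pools neutral and loss.

# Dose-response estimation

Each plate is standardised by dividing all raw signals by the median
signal of that plate's control wells, so fully viable wells read 1 and
results are invariant to overall signal scale. The per-well procedure
follows three steps:

1. **Outlier screen.** Standardised responses are fitted as a degree-4
   polynomial in natural-log dose by robust M-estimation, and wells with
   a final robust weight below 0.4 (weights in [0, 1]) are flagged as
   outliers. The estimator is a two-stage iteratively reweighted least
   squares: a monotone Huber pass starting from ordinary least squares,
   then a redescending Tukey bisquare pass (tuning constant 4.685, 95%
   Gaussian efficiency) started from the Huber weights. The residual
   scale is the zero-centred MAD *floored at 0.05 standardised units*
   (about a typical assay coefficient of variation, configurable). The
   floor is essential: on near-noiseless plates the degree-4
   polynomial's smooth lack-of-fit would otherwise drive a
   high-breakdown scale estimate toward zero and flag entire dose
   groups of clean wells. With the floor, a pilot simulation at the
   generator's default settings detects a single 5-fold spike among 24
   wells — and nothing else — in 98% of 200 seeds, and never flags a
   clean or constant plate.
2. **M-spline fit.** After removing flagged wells the responses are fit
   by least squares on a cubic M-spline basis of log dose over the
   observed range, with interior knots at quantiles of the distinct log
   doses (`max(1, n_distinct - 4)` knots). M-splines span the same
   space as clamped B-splines, so constants and straight lines are
   represented exactly. Replicates enter as individual points — never
   averaged — to preserve the per-well semantics of the outlier rule.
   No monotonicity constraint is imposed by default; a monotone
   non-increasing variant (intercept plus non-positively weighted
   I-splines) is available.
3. **AUC and IC50.** The AUC is the integral of the fitted curve over
   the log-dose range, evaluated exactly through the I-spline
   antiderivative ($I_i(x) = \sum_{j>i} B_{j,k+1}(x)$), and divided by
   the log-dose range so a constant-1 curve has AUC 1 and AUCs are
   comparable across drugs with different ranges. The IC50 is the
   lowest dose where the fitted curve crosses 0.5 (bisection after a
   513-point grid scan; the first crossing wins if there are several);
   when the curve never reaches 0.5 in range the IC50 is censored. A
   five-parameter log-logistic fit (Levenberg–Marquardt) serves as a
   cross-check, reporting its own AUC/IC50 on the same conventions and
   the discrepancy from the spline estimates.

Internally doses are on the natural-log scale; since the AUC is
normalised by the log-dose range, results are invariant to the log
base.

## Known limitation

A steep response curve (Hill slope well above ~1 on the log10 scale)
defeats the degree-4 polynomial pre-fit: its lack-of-fit exceeds
realistic assay noise, and the robust screen then distrusts wells near
the transition. This is a property of the polynomial pre-fit procedure
itself, not of the implementation; the scale floor mitigates but does
not remove it. The plate generator's default truth slope (1.2 per
natural-log unit, Hill ≈ 0.5 — a shallow curve typical of primary
spheroid viability assays) was fixed after that pilot and then frozen.

# Resampling statistics

All Monte-Carlo p-values use the add-one rule $p = (b+1)/(B+1)$ with
ties counted as at least as extreme; exact enumerations report exact
proportions. Highlights and choices:

* **Permutation mean-difference test** (one-sided): permutes group
  labels; switches to exhaustive subset enumeration when the number of
  assignments is at most $10^5$. A patient-resampling variant
  (`permutation_cooccurrence_test`) permutes marker status across
  samples and re-derives per-gene frequency differences, for
  marker-stratified co-occurrence questions.
* **Bootstrap set comparison** (one-sided): percentile bootstrap of the
  mean difference between two sets of correlations; the tail definition
  (percentile rather than basic) is a documented choice.
* **Jonckheere–Terpstra trend test**: Mann–Whitney counts summed over
  ordered group pairs, mid-ranks (weight 1/2) for ties. Exact by full
  multinomial enumeration when arrangements ≤ $10^6$; otherwise
  Monte-Carlo permutation or a tie-corrected normal approximation,
  selectable and logged.
* **Null simulation study**: for pre-registration of gene–drug
  associations, draws independent drug-response (standard normal) and
  copy-number (uniform over 1–6) matrices at 20 patients × 12 drugs ×
  5–10 genes and summarises the span of absolute pairwise Pearson
  correlations. The discrete copy-number marginal is a documented,
  configurable choice; the target statistic is insensitive to marginal
  shape at this sample size. Expected behaviour: the per-replicate
  maximum averages near 0.6 — large enough that unconstrained
  gene–drug screens at this scale would be dominated by spurious hits.
* **GSEA**: classic weighted running sum (weight = |statistic|,
  exponent 1); ES is the maximal deviation; NES divides by the mean
  |ES| of same-sign gene-label permutations (the common convention);
  the two-sided p-value is the add-one fraction of same-sign
  permutation scores at least as extreme.
* **Ordered association**: linear-by-linear statistic $(N-1)r^2$ with
  equally spaced integer scores on both ACN margins, chi-square with
  1 df; the unordered Pearson chi-square is reported alongside.
* **KS uniformity sensitivity**: one-sample Kolmogorov–Smirnov of
  observed association p-values against Uniform(0,1), situated within
  the null distribution of KS p-values from random same-size sets
  drawn from a candidate universe.
* **Pre-specified association tests**: per (gene, drug, direction)
  spec, a one-sided Wald t-test of the AUC-on-RCN slope and a
  one-sided Jonckheere–Terpstra test across 3-level ACN, both in the
  pre-registered direction; sample exclusions (non-independent repeat
  samples, high-variability samples) are explicit arguments. No
  multiplicity correction is applied within a pre-registered set;
  Benjamini–Hochberg remains available for exploratory sweeps via
  `p.adjust`.

Where the permuted unit is ambiguous (gene labels versus patients), the
package implements both: the plain two-set test permutes the supplied
per-gene values, and the patient-level variant resamples samples.

# Synthetic data: what it emulates and what it does not

The generators mirror the statistical structure the analyses assume:

* **Multi-region cohort** (`simulate_multiregion_cohort`): 30 patients
  by default with 2–6 regions each (median 4, matching a typical
  multi-region series), base ploidy drawn from {2, 3, 4} (HGSOC is
  frequently whole-genome duplicated), about six clonal and six
  subclonal events per patient (Poisson), exponential event lengths
  with mean 30 Mb on a compact six-chromosome genome. Gains add
  `ceiling(ploidy/2)` copies to the major allele and losses remove the
  minor allele (an LOH loss to `floor(ploidy/2)` total), so every
  planted event clears its classification threshold with margin at
  zero noise and recovery degrades smoothly as `cn_noise_sd` grows.
  Noise is additive Gaussian on each raw allele copy number, truncated
  at zero — the simplest symmetric error model, with one knob
  controlling recovery difficulty; the default (0.1) is a plausibility
  choice, not a calibration against any measured error magnitudes. Subclonal events occupy a uniformly chosen strict
  nonempty proper subset of regions.
* **Drug plates** (`simulate_plate`): 8-point half-log dilution series,
  technical triplicates, 16 controls drawn at the truth upper
  asymptote, multiplicative noise with CV 5%, truth curves from a
  five-parameter log-logistic. Truth AUC comes from adaptive
  quadrature of the closed-form curve and truth IC50 from its exact
  root; outliers are multiplicative spikes at logged indices.
* **Cohort genotypes** (`simulate_cohort_genotypes`): a planted
  co-occurrence between marker (MYC) gain/amplification and PI3K/RAS
  pathway SCNAs, expressed as a log-odds increment over a baseline
  alteration rate; genes outside the pathway are unaffected.
* **Expression/CN/methylation** (`simulate_expression_cn`): expression
  is a per-group linear effect of copy number plus Gaussian noise;
  methylation is negatively coupled to that effect on the logit scale,
  emulating the pattern that strongly CN-driven genes are
  hypomethylated.

What the generators do **not** emulate: breakpoint mechanisms, purity
and subclonal mixtures within a region, read-level noise, wavy GC
biases, linkage between neighbouring genes, or plate spatial effects.
Passing the recovery and calibration suites therefore demonstrates
correctness of the algorithms under the stated statistical model — not
performance on real sequencing data.

# Problem sizes and numerical choices

The validation suites use 20–30 patient cohorts, 100–200 simulated
plates, permutation sizes of 1000–2000 and 200-replicate calibration
loops — sizes chosen so the full suite runs in minutes on a laptop
while keeping Monte-Carlo error well inside the asserted tolerances
(the binomial 95% band for 200 calibration replicates at α = 0.05 is
4–16 rejections). Degenerate inputs are handled explicitly: empty
groups, single-region patients, constant responses (zero residual
scale), singular covariance (degenerate ellipse), curves that never
cross 0.5 (censored IC50), fewer than 4 distinct doses after outlier
removal (censored fit), and non-convergent 5PL fits (spline estimates
reported, flagged).

# Reproducibility

Every generator and every resampling test takes an explicit integer
seed, seeds the global RNG once, and draws in a fixed documented
order; identical configs are bit-reproducible. `run_pipeline()` writes
a manifest (package version, config digest, input checksums, per-stage
seeds) with every run.
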