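---
title: "Cohort metrics for colorectal cancer genomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort metrics for colorectal cancer genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcmetrics)
```

# Scope

`crcmetrics` packages the cohort-level classification and association
machinery used in population-scale colorectal cancer (CRC) genome and
transcriptome studies. Raw patient-level data in such studies are access
restricted, so every procedure here is exercised against a seeded synthetic
cohort generator that plants the structure the methods are designed to
detect. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology left
genuine freedom. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

# Hypermutation classification

Colorectal tumours split into a hypermutated class (HM; mostly
microsatellite-instable or *POLE*-mutant) and a non-hypermutated class
(nHM). The classifier works on total somatic short-variant counts
$N_{\mathrm{SNV}}$ and flags a sample when

$$N_{\mathrm{SNV}} > N_{\mathrm{median\_SNV}} + 1.5 \times \mathrm{IQR}.$$

Because a handful of extreme tumours distort the quartiles, the rule is
applied iteratively: each flagged sample is replaced in the pool by two
artificial samples carrying half its count, and the threshold is recomputed
on the updated pool until a round flags nothing. A sample is HM iff it or
any artificial descendant was ever flagged; `outlier_times` counts the
flagging rounds.

Decisions taken where the formulation is silent:

* **Quantile convention.** Median and quartiles by linear interpolation at
  positions $(n-1)p$ (`quantile(type = 7)`), the default of mainstream
  statistical environments. Pinned so the worked examples in the tests are
  exact (e.g. the five-sample cohort `100, 110, 120, 130, 5000` has a
  round-1 threshold of 150 and a round-2 threshold of 2817.5).
* **Strict inequality.** The printed rule is a strict `>`; a cohort of
  identical counts therefore flags nobody (zero IQR).
* **Odd splits.** "Equal number of mutation counts" is impossible for odd
  counts; we use `floor`/`ceiling` halves so the total count is conserved.
* **`outlier_times` counts rounds, not descendants.** "How many times a
  sample was called" reads most naturally per round; with descendants the
  count would depend on the exponentially growing number of artificial
  samples.
* **Pool composition.** Thresholds are recomputed on the full updated pool
  including artificial samples.

Each split halves the pool maximum, so the procedure terminates after at
most $\lceil \log_2 \max N \rceil + 1$ rounds — asserted as an invariant in
the tests.

TMB is reported as count over genome megabases; the default denominator of
2,859 Mb (non-gap GRCh38 autosomes plus X) is exposed as a parameter
because published mutations-per-megabase cutoffs depend on it. The MSI call
is a boundary-inclusive threshold (default 3.5) on a paired-sample
instability score.

# Pairwise co-mutation testing

For every gene pair in a binary genes-by-samples matrix, a two-sided
Fisher's exact test (via `stats::fisher.test`, which sums hypergeometric
probabilities no larger than the observed table's) with Benjamini–Hochberg
adjustment across pairs (significance at FDR < 0.1). The reported odds
ratio is the cross-product ratio $\frac{ad}{bc}$, the quantity clinicians
read off the 2×2 table, not the conditional-MLE estimate; pairs with
OR > 1 are co-occurring, the rest mutually exclusive. Tests validate the
p-values against a full hypergeometric enumeration oracle for all margins
up to 30.

# Copy-number states and density metrics

Allele-specific segments (total copy number `tcn`, minor copy number
`lcn`) map to eight states: wild type (2,1), homozygous deletion (0,0),
LOH (1,0), copy-neutral LOH (2,0), gain-LOH (3–4, 0), gain (3–4, ≥1),
amp-LOH (≥5, 0) and amp (≥5, ≥1). Allele-specific callers can leave `lcn`
unresolved at low coverage; rather than dropping such segments (which would
bias genome-altered fractions) we coarse-label from `tcn` alone and set an
`lcn_indeterminate` flag. Focal amplification/deletion calls use strict
log2-ratio thresholds (> 0.9, < −0.3).

Density metrics per sample: fractions of the genome gained, lost and
altered (PGA) plus average aberrant segment lengths and gain:loss ratios.
Two open choices, both documented in the API:

* **Aberration baseline.** PGA is computed against diploid (`tcn != 2`) by
  default — the simplest reading of "total copy-number aberration"; a
  ploidy-relative variant (length-weighted modal `tcn`) is exposed as an
  option.
* **Ratios with zero denominators** are reported as missing rather than 0
  or infinity. PGA is invariant to segment splitting; average lengths are
  segment-definition-dependent by construction and documented as such.

# Mitochondrial variant filtering

Deep WGS covers the mitochondrial genome thousands-fold, so very low
heteroplasmy is detectable — and so are artifacts from nuclear-embedded
mitochondrial segments (NuMTs), which present as recurrent low-VAF calls
supported in the matched control. A candidate is retained iff:

1. control VAF < 0.0034;
2. the allele-rate ratio
   $r = \frac{N_{\mathrm{MutCtrl}}/RD_{\mathrm{Ctrl}}}
   {N_{\mathrm{MutCtrl}}/RD_{\mathrm{Ctrl}} + N_{\mathrm{MutTum}}/RD_{\mathrm{Tum}}}$
   is < 0.0629 (NuMTs contaminate both compartments, pushing $r$ towards
   0.5; true somatics sit near 0). Both cutoffs were originally derived as
   median + 2 × IQR of the candidate distribution — `derive_cutoff()`
   reproduces that derivation under the same pinned quantile convention;
3. for low-heteroplasmy candidates (tumour VAF < 0.10), the variant's
   cohort carrier frequency is < 0.023 — applied only below 10%
   heteroplasmy so recurrent true hotspots are not deleted, and with
   tumours (not candidate rows) as the denominator;
4. tumour VAF lies strictly inside the heteroplasmy window (0.01, 0.95).

A false-negative guard then re-examines variants with cohort
$\mathrm{VAF_{max}} < 0.1$ and $\mathrm{VAF_{median}} < 0.05$ and retains
only carriers above 5% heteroplasmy; it runs after the recurrence filter
and can re-admit carriers the recurrence rule removed. When both alt
counts are zero the ratio statistic is undefined; such candidates pass the
ratio rule trivially (there is no evidence of control support), which is
flagged in the report. Variants above 60% VAF are banded near-homoplasmic.

mtDNA copy number: `raw = 2 × mt_depth / autosomal_depth`. The
purity adjustment in the literature is cited without equations, so the
package pins its own declared formula,
`normalized = (raw_tum − (1 − purity) × raw_ctrl) / purity`, isolated in
one function — with `purity = 1` (or no control reference) it reduces to
the raw value.

# Hypoxia scoring and associations

The Buffa score sums, over a hypoxia signature gene set, +1 when a
sample's abundance is strictly above the gene's median over tumour samples
and −1 otherwise. Two pinned choices: ties at the median score −1
(the rule says "above"), and reference medians always come from tumour
samples only, also when scoring controls. Being a rank statistic, the
score is invariant under monotone per-gene transformations — property
tested, and important because it makes the score robust to expression
normalization choices.

Associations between hypoxia and 22 mutational-density metrics (10 variant
counts, 8 copy-number densities, 4 SV counts) use nested Gaussian linear
models,

$$\mathrm{full}: \mathrm{hypoxia} \sim \mathrm{feature} + \mathrm{age} +
\mathrm{sex} + \mathrm{purity}, \qquad
\mathrm{null}: \mathrm{hypoxia} \sim \mathrm{age} + \mathrm{sex} +
\mathrm{purity},$$

compared by an F-test (ANOVA). Multiple testing uses Bonferroni when fewer
than 20 tests were conducted and Benjamini–Hochberg otherwise, with
significance at adjusted p < 0.1. Missing covariates are handled by
complete-case analysis with logged exclusion counts. Model adequacy is
checked by parametric simulation (default 250 replicates, explicit seed):
each observation's scaled residual is its quantile among responses
simulated from the fitted model, and the scaled residuals are tested
against Uniform(0,1) by Kolmogorov–Smirnov; ties are assessed with a small
numerical tolerance so an exact fit degenerates cleanly to residuals of
0.5 (which the KS test then rejects, as it should).

# Signature similarity and activity correlation

Profiles are probability vectors over fixed channel sets; they are
re-indexed by channel label on read, never compared by storage position. A
de novo signature is novel iff its best cosine similarity to *each* of two
reference catalogues is strictly below 0.85 — monotone in the threshold.
Activity correlations are Spearman over signature pairs with BH adjustment
(FDR < 0.05); ties get average ranks, and p-values use exact enumeration
below 10 untied samples and the t-approximation otherwise.

# Survival machinery

Endpoints follow registry definitions: OS from diagnosis to death
(censored at last follow-up), RFS from surgery to the earliest of
recurrence or death (stage IV at diagnosis excluded), SAR from recurrence
to death. Times are in years of 365.25 days. The derivation is total —
every patient gets every endpoint row with an eligibility flag — so
downstream filters are explicit rather than silent.

The maximally selected rank statistic scans all dichotomizations of a
continuous marker that leave at least 10% of the cohort on each side
(candidate cutpoints are midpoints between consecutive distinct values,
standard maxstat practice) and maximizes the standardized log-rank
statistic, computed as a linear rank statistic with log-rank (Peto) scores
and the permutation variance. No small-sample correction is applied to the
selected statistic: the operation reports the cutpoint, not an inference
on it. The Cox workflow screens features univariably at p < 0.05 and
refits survivors with the clinical covariates (site, pretreatment, stage,
age group, grade); hypermutation status is configurable as an additional
covariate and off by default, since the stratified analyses it would
adjust for are run separately per burden class.

# The synthetic cohort generator

`generate_cohort()` draws, under one locally seeded RNG stream with no
global side effects: per-sample mutation counts with a planted HM
subpopulation; MAF-like variant records; non-overlapping allele-specific
segments spanning the eight states (fewer copy-number events in HM
tumours); mitochondrial candidates mixing private true somatics (control
alt count ≈ 0) with NuMT-like artifacts (control-supported, tumour VAF
below 0.1, carried by 15% of the cohort); an expression matrix whose
signature genes are shifted one residual standard deviation upward in a
planted high-hypoxia subgroup; clinical tables with ordered dates and
exponential survival at hazard ratio 3 above the 40th percentile of a
continuous marker, censored administratively at a fixed data-lock date;
and structural-variant counts with the class imbalances seen between HM
and nHM tumours. Mitochondrial depths are uniform on [500, 30000] to span
the deep-coverage regime of mtDNA in WGS.

Choices worth recording:

* **Baseline burden distribution.** Baseline log counts are drawn
  *log-uniform* (bounded multiplicative spread with the configured
  log-scale sd), not log-normal. For any baseline with Gaussian-or-heavier
  log tails, the threshold `median + 1.5 × IQR` sits at a fixed ~97–99th
  percentile, so a percent-level fraction of baseline samples would always
  be flagged and the planted HM truth could never be recovered exactly.
  A bounded spread keeps the counts overdispersed relative to Poisson
  (about a 2.8-fold range at the default sd of 0.3) while placing the
  entire baseline below the threshold, which is what makes
  truth-recovery testing of the classifier meaningful.
* **Censoring** is administrative at the data-lock date — the simplest
  mechanism consistent with registry follow-up.
* **Determinism.** Identical configuration and seed give byte-identical
  cohorts and, through `write_cohort()`, byte-identical files with stable
  checksums.

What the generator does *not* emulate: read-level data, realistic
trinucleotide contexts, linkage between tables beyond the planted effects,
correlated covariates, or informative censoring. Passing tests on this
cohort therefore demonstrate that each procedure recovers the structure it
is specified to detect, not that it is robust to every pathology of real
sequencing data.

# Problem sizes and numerical checks

The test-suite and acceptance script use deliberately scaled problem
sizes, chosen as the smallest cohorts at which the planted effects are
unambiguous: 20 seeded cohorts of 200 samples for burden classification,
20 cohorts of 100 samples for the mitochondrial filter, 1,000 null and 500
powered simulations of 200 samples for the association framework's type-I
error and power, 100 simulations of 500 subjects for cutpoint recovery,
and exhaustive enumeration wherever it is feasible (all copy-number states
with `tcn` ≤ 10; all 2×2 tables with margins ≤ 30; all 720 rank
permutations at n = 6). Oracles are naive reimplementations — lookup
tables, double loops, enumeration — sharing no code with the package
internals.

```{r}
res <- classify_hypermutation(c(s1 = 100, s2 = 110, s3 = 120, s4 = 130,
                                s5 = 5000))
res$samples
res$threshold_trace
```

# Known limitations

* The mtDNA copy-number purity adjustment is this package's own pinned
  formula; published normalizations based on unavailable code may differ.
* PGA defaults to a diploid baseline; genome-doubled tumours are better
  served by the ploidy-relative option.
* The maxstat scan reports no multiplicity-corrected p-value for the
  selected cutpoint.
* Cohort-specific quantities of real studies (driver hazard ratios,
  score medians by site) are data-dependent and out of scope; the package
  reproduces procedures, not restricted datasets.
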