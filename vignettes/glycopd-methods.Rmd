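---
title: "Methods: the glycopd association pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the glycopd association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopd)
```

# Scope

`glycopd` implements a two-cohort case-control association workflow for
HILIC-UPLC N-glycomics panels: chromatogram quantification on the
glucose-unit (GU) scale, compositional normalisation with empirical-Bayes
batch correction, derived glycan trait computation, covariate-adjusted
per-cohort association models, inverse-variance random-effects
meta-analysis and Benjamini–Hochberg FDR control. Because subject-level
glycomics cohorts are rarely public, the package treats its synthetic-data
generator as a first-class module: it emulates the two-cohort COPD
case-control design (discovery cohort of 137 cases / 95 controls,
replication cohort of 61 / 148) with known injected effects, so the
pipeline's calibration — type-I error, FDR, and parameter recovery — can
be measured rather than assumed.

# Chromatogram quantification

Retention times are mapped to glucose units through a calibration fitted
to a hydrolysed glucose-oligomer (dextran) ladder. We use a
shape-preserving monotone piecewise-cubic interpolant (Hyman-filtered
spline) for the GU→RT map rather than a polynomial fit: monotonicity
guarantees invertibility, and the RT→GU inverse is obtained by numeric
root finding so the round trip is exact to numerical precision across
the calibrated range. Queries outside the ladder use linear extrapolation
with the endpoint slope and are flagged.

Peaks are quantified by trapezoidal integration of the fluorescence
trace inside fixed half-open GU windows `[lo, hi)` shared by all samples,
with linear sub-sample interpolation at the window edges; this mirrors
the practice of keeping the same integration intervals for every sample
so that peak definitions are comparable across runs. The true window
boundaries of GP1–GP39 / IGP1–IGP24 are instrument- and run-specific and
are not published, so the bundled schemes are *synthetic* equal-width
(0.25 GU) placeholders with the correct panel sizes; real analyses must
substitute measured schemes (`default_integration_scheme(file = ...)`).
Baseline subtraction is out of scope: the synthetic renderer generates
baseline-free sums of Gaussians, and the render→integrate round trip is
an approximate identity (≤ 0.5% per peak at zero noise, dominated by the
Gaussian tails outside the window at the default width of 0.03 min
against ~0.3 min windows, and by trapezoid error on the 0.002 min grid).

# Preprocessing

Raw areas are normalised to percent of total chromatogram area (making
each subject's vector compositional, summing to 100), log-transformed,
batch-corrected, and exponentiated back. The stage order is enforced by
a scale flag on the matrix container; calling a stage out of order is an
error, and every applied step is appended to a provenance log.

Zeros in relative-area data are instrument-censoring artifacts rather
than true absences, so values below a floor (default `1e-4` percent) are
floored before the log; every flooring event is recorded.

Batch correction uses the parametric empirical-Bayes location/scale
model (ComBat, via the sva package): per-peak standardisation against a
pooled fit, batch means shrunk toward a normal prior and batch variances
toward a moment-matched inverse-gamma prior. Two deliberate choices:

* **Grand-mean restoration.** The EB shrinkage leaves the
  batch-size-weighted mean of the adjusted batch effects slightly
  non-zero, so raw ComBat output can drift a peak's grand mean. The
  overall location is not identified by the batch model, so
  `combat_adjust()` re-centres each peak to its pre-adjustment grand
  mean. This keeps back-transformed row sums near 100 and makes the
  grand mean exactly invariant; it has no effect on any association
  model, which all include an intercept.
* **No biological covariates by default.** Whether the original
  analyses protected case/control status in the batch design is not
  stated; the default batch model is unsupervised, and a
  `protect_status` flag adds status to the design for users who prefer
  the protected variant. Batch correction is always applied per cohort;
  cohorts are only ever combined through the meta-analysis.

A single batch returns the input unchanged (with a warning), and batches
of one subject are rejected. Back-transformation deliberately does *not*
re-close rows to 100: re-closure would re-introduce compositional
coupling that the batch adjustment just removed, and the adjusted row
sums (typically within 100 ± 1) are recorded in the provenance instead.

# Derived traits

Each derived trait is an exact linear combination of peaks with weights
1 or 1/2; the 1/2 applies to GP2, whose window co-elutes an oligomannose
and an agalactosylated structure and is split evenly between the two
classes. Definitions live in a version-controlled CSV
(`panel, trait, peak, weight`) rather than code, so the transcription is
reviewable; `load_trait_definitions()` validates names and weights on
load. Traits are computed on the back-transformed percent-adjusted scale
— a sum of proportions is only meaningful on a linear scale.

The trait system implies structural identities that `validate_partitions()`
checks exhaustively: for plasma, the galactosylation classes (G0–G4), the
sialylation classes (S0–S4) and the branching classes (LB, HB) each,
together with OligoMan, cover all 39 peaks with total weight exactly 1;
for IgG, G0+G1+G2 and S0+S1+S2 each cover all peaks except IGP20. IGP20
belongs to no galactosylation or sialylation class in the published trait
system; whether that is intentional cannot be determined from the printed
formulas, so it is implemented verbatim and validated as weight 0.

# Association models

All continuous variables — each glycan, age, and continuous clinical
features — are transformed within cohort by the rank-based inverse-normal
transformation `Φ⁻¹((r − ½)/n)` with average ranks for ties (the GenABEL
convention; a Blom offset is available behind a flag). Transforming
within cohort puts effects in SD units and makes them comparable across
cohorts, which is what justifies pooling them.

Case-control models are logistic regressions
`status ~ glycan + age + sex`, fitted by the package's own IRLS
(tolerance `1e-8` on the coefficient change, 25 iterations max), with
Wald standard errors from the observed information and two-sided normal
p-values. Complete separation — any coefficient beyond ±15 on the logit
scale, or non-convergence — flags the result and sets p to `NA` instead
of reporting a spuriously extreme value. Sex enters as a 0/1 indicator
(referent female).

Clinical-feature models treat the glycan as the dependent variable:
`glycan ~ feature + age + sex` by ordinary least squares with t-based
Wald p-values (`df = n − p`). Categorical features are coded against a
referent — healthy controls for the case-only severity features (GOLD
stage, ABCD group, exacerbation category), never-smokers for smoking —
with one contrast row per non-referent level; levels with fewer than 3
subjects are skipped and flagged. The wording of the source analysis is
slightly ambiguous about whether severity analyses modelled the glycan
or the status as dependent; the GLM (glycan-dependent) reading is
implemented, with the logistic variant retained for the status analysis.

Cohort descriptives follow the conventional case-control table: median
(IQR) with a Wilcoxon rank-sum test for continuous variables (exact
enumeration when the combined n is ≤ 12 without ties, otherwise the
normal approximation with tie and continuity corrections), N (%) with
Fisher's exact test for categorical ones (2×k by the exact network
algorithm for k ≤ 3 at moderate n, seeded Monte-Carlo beyond), and no
test for case-only variables.

# Meta-analysis and FDR

Per-cohort effects for the same (variable, feature, level) are pooled by
inverse-variance random-effects meta-analysis with weights
`1/(se² + τ²)`. With two cohorts τ² is weakly identified; REML (via
metafor, iterative with τ² floored at 0) is the default, falling back to
the DerSimonian–Laird closed form on non-convergence, and each pooled
row is tagged with the estimator actually used. Flagged per-cohort fits
are excluded before pooling; variables present in only one cohort are
emitted with `k = 1` and excluded from FDR adjustment.

BH adjustment is applied within reporting families — panel ×
directly-measured/derived × analysis feature — matching the convention
of reporting those tables separately; a single global family is
available behind a flag. Significance is declared at adjusted p < 0.05.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Composition model.** Log abundances are drawn i.i.d. normal
  (default SD 0.25) around a fixed smooth baseline profile and closed to
  100% — a logistic-normal rather than Dirichlet model, chosen so batch
  and case effects are additive on exactly the scale where the pipeline
  removes or estimates them. The baseline profile is a synthetic smooth
  curve with plausible dominant-peak structure, not an estimate of any
  real cohort; the per-peak dispersion is homogeneous, so the generator
  does not reproduce the peak-specific variance heterogeneity or the
  correlation structure of real glycomes. Passing calibration tests
  therefore demonstrates correctness of the pipeline's statistics under
  a clean compositional model, not robustness to every feature of real
  data.
* **Effect injection and calibration.** A case-control effect of *e* SD
  on a trait is injected as a log-scale mean shift on the trait's member
  peaks (weighted by the trait coefficients). Because closure couples
  all peaks, the shift size is calibrated by a pilot Monte-Carlo (400
  draws) with one Newton refinement so the realized trait difference
  lands at *e* control-SDs; with several simultaneous effects each is
  calibrated independently, so joint targets are approximate by
  construction. For a near-normal marker with equal group variances the
  logistic log-OR per SD approximately equals the standardized mean
  difference, which is why the pipeline's pooled estimate recovers the
  injected value (the rank-INT of the case-control mixture attenuates it
  by ~3% at e = 0.5 — well inside the ±0.15 acceptance band used in the
  calibration tests).
* **Covariates.** Cases are older, more often male and more often
  (ex-)smokers, with per-cohort distributions anchored at the published
  medians and frequencies; spreads are plausible placeholders since the
  source does not print them. Sex is assigned as an exact rounded count
  per group, so the default-size simulation reproduces the printed
  discovery-cohort sex table (and hence its Fisher p = 0.105) exactly.
  Glycan–covariate correlations beyond the configured smoking effects
  are not simulated — the published work does not report their
  magnitudes, so any value would be an invention.
* **Severity grading.** Case effects are multiplied by a per-GOLD-stage
  dose (default 0.7/0.9/1.1/1.3), normalised by the mean dose over the
  simulated cases so the average case still carries the nominal effect;
  this yields the "glycome shift grows with stage" pattern without
  decalibrating the case-control effect.
* **Batch artifacts** are an additive per-batch/peak shift
  (default SD 0.2) plus a multiplicative effect on centred values
  (log-SD 0.05), both drawn on the log scale and recorded in the truth
  object.
* **Randomness.** Everything derives from one integer seed; identical
  configurations produce byte-identical tables.

Default effect magnitudes (0.25–0.4 SD, in the replicated directions:
lower LB/G1, higher HB/G4/S3/S4/AntF in cases; lower IgG G1, higher
bisecting GlcNAc) were chosen once as moderate, field-typical values —
the source cohorts' standardized effect sizes are not public — and are
fully configurable per run.

# Numerical choices and problem sizes

* IRLS tolerance `1e-8` / 25 iterations; REML tolerance per metafor
  defaults with a 200-iteration cap; separation threshold |β| > 15.
* GU inversion by `uniroot` at tolerance `1e-12`; chromatogram grid
  0.002 min.
* Calibration studies in the tests and the acceptance script use two
  cohorts of 500 cases / 500 controls with 20 replicates — large enough
  that the estimator's Monte-Carlo SE (~0.01 for the pooled effect mean)
  is far inside the ±0.15 recovery band, while the full 40-replicate
  battery completes in about two minutes on one CPU.
* The Wilcoxon exact branch switches to the normal approximation above a
  combined n of 12 or in the presence of ties, matching the behaviour of
  the classical tables.

# Known limitations

* The bundled integration schemes and the ladder are synthetic; real
  chromatogram quantification requires measured windows and a measured
  ladder.
* The generator's homogeneous dispersion and lack of between-peak
  correlation understate the collinearity of real glycan panels; FDR
  calibration under strong dependence is not tested here.
* τ² from two cohorts is weakly identified; pooled intervals should be
  read accordingly (the DL/REML choice is surfaced per row).
* Non-parametric ComBat priors, reference-batch ComBat and missing-value
  imputation are out of scope; complete peak matrices are assumed.
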