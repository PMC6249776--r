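# glycopd

Two-cohort case-control association analysis of plasma-protein and IgG
N-glycomics data, of the kind used to study chronic obstructive pulmonary
disease (COPD). The package covers the full path from HILIC-UPLC
chromatograms to FDR-controlled meta-analytic effect estimates, and ships
a synthetic-data generator that emulates the two-cohort study design so
every stage can be exercised and calibrated without subject-level data.

## The problem and the model

N-glycans released from plasma glycoproteins separate into 39
chromatographic peaks (GP1–GP39), and those released from IgG into 24
(IGP1–IGP24); each peak is quantified as a percentage of the total
integrated chromatogram area, with retention times calibrated to glucose
units (GU) against a dextran ladder. Peaks sharing a structural feature
are combined into derived traits — e.g. low branching (LB), mono- to
tetragalactosylation (G0–G4), sialylation (S0–S4), bisecting GlcNAc, core
and antennary fucosylation — as fixed linear combinations with weights 1
or 1/2 (the co-eluting GP2 is split between its two classes).

The statistical pipeline follows the standard glycomics design:

1. **Preprocessing** — total-area normalisation, natural-log transform,
   and parametric empirical-Bayes (ComBat) batch correction per cohort;
   traits are computed on the back-transformed linear scale.
2. **Per-cohort association** — every glycan variable (and age) is
   mapped to the standard normal by rank-based inverse-normal
   transformation, `y_i = Φ⁻¹((r_i − ½)/n)`, then modelled as
   `status ~ glycan + age + sex` (logistic regression; the glycan
   coefficient is a log odds ratio per SD) or
   `glycan ~ feature + age + sex` (general linear model) for clinical
   features such as GOLD stage, ABCD group, exacerbation frequency,
   smoking or FEV1/FVC, against a referent group.
3. **Meta-analysis** — per-cohort effects are pooled by inverse-variance
   random-effects meta-analysis, `w_i = 1/(se_i² + τ²)` with τ²
   estimated by REML (DerSimonian–Laird as fallback/alternative), and
   the false discovery rate is controlled with Benjamini–Hochberg within
   each reporting family (panel × measured/derived × feature).

The logistic and linear fitters are implemented in the package (IRLS and
QR least squares, Wald inference, explicit separation flagging); batch
correction and τ² estimation delegate to `sva::ComBat` and
`metafor::rma.uni`.

## A worked example

Simulate two cohorts of 60 cases / 60 controls on the IgG panel with a
single injected effect — a 0.5 SD deficit of monogalactosylated glycans
(G1) in cases — and run the full pipeline:

```r
library(glycopd)

cfg <- sim_config(panel = "igg",
                  n_cases_per_cohort = c(60, 60),
                  n_controls_per_cohort = c(60, 60),
                  effect_map = c(G1 = -0.5),
                  smoking_effect_map = c(), seed = 42)
res <- simulate_and_run(cfg, include_peaks = FALSE)
m <- res$meta[res$meta$feature == "status",
              c("variable", "beta", "se", "tau2", "p", "p_adj", "significant")]
print(m[order(m$p), ], digits = 3, row.names = FALSE)
```

```
  variable    beta    se   tau2       p  p_adj significant
        G1 -0.5011 0.170 0.0000 0.00316 0.0284        TRUE
     CoreF -0.2746 0.159 0.0000 0.08442 0.3799       FALSE
        S1 -0.3580 0.246 0.0690 0.14558 0.4323       FALSE
        G0  0.2063 0.158 0.0000 0.19213 0.4323       FALSE
        S0  0.1179 0.152 0.0000 0.43940 0.6722       FALSE
        G2  0.1180 0.157 0.0000 0.45087 0.6722       FALSE
  OligoMan  0.2756 0.431 0.3097 0.52284 0.6722       FALSE
        S2  0.0968 0.209 0.0338 0.64320 0.7236       FALSE
 Bisecting  0.0452 0.155 0.0000 0.77004 0.7700       FALSE
```

The injected trait is recovered at its true magnitude (pooled log-OR
−0.50 per SD, i.e. cases have about 0.5 SD less G1), it is the only
trait surviving BH adjustment (`p_adj = 0.028 < 0.05`), and `tau2 = 0`
indicates no between-cohort heterogeneity for it. Correlated traits
(CoreF shares peaks with G1) show attenuated, non-significant shifts —
the compositional coupling a real glycome would also show.

The same workflow is available from the shell:

```sh
Rscript inst/cli/glycopd.R all --config inst/extdata/demo_config.yaml --seed 3 --out out/
```

which writes `peaks.csv`, `phenotypes.csv`, `truth.json`,
`adjusted.csv`, `traits.csv`, `results_assoc.csv`, `results_meta.csv`,
`descriptives.csv` and a reproducibility manifest.

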