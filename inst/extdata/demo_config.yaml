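# Small demo configuration: two cohorts of 15 cases / 15 controls on the
# IgG panel, two batches per cohort, one injected monogalactosylation
# deficit. Runs the full pipeline in seconds.
panel: igg
include_peaks: true
sim:
  n_cases_per_cohort: [15, 15]
  n_controls_per_cohort: [15, 15]
  n_batches_per_cohort: 2
  batch_shift_sd: 0.2
  batch_scale_sd: 0.05
  effect_map:
    G1: -0.5
  smoking_effect_map: {}
features:
  smoking: categorical
preprocess:
  floor: 1.0e-4
meta:
  method: REML
  family_policy: per_family
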