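# Example configuration for runPipeline(): a reduced synthetic study.
# Any field omitted here falls back to defaultPipelineConfig().
seed: 1
simulate:
  n_per_class:
    GH: 60
    CE: 10
    non-CAZyme: 500
  group_sizes:
    CS_CONTROLLED: 15
    XYR1_SPECIFIC: 6
    OTHER_SPECIFIC: 2
    XYR1_CS_CO: 2
    OTHER_CS_CO: 1
  n_reps: 3
  dispersion: 0.05
  library_size_mean: 2.0e7
thresholds:
  min_abs_log2fc: 2
  max_p: 0.01
  min_expr: 2
  pseudocount: 1
classifier:
  expr_floor: 2
  level_ratio_min: 2
  level_p: 0.01
secretome:
  noise_cv: 0.2
  n_reps: 3
  enrich_fold: 1.9
  enrich_p: 0.01
  high_cutoff_pct: 1
activity:
  plateau_U: 3.84
  rate: 0.5
  t_mid: 8.2
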