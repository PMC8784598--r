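# Demonstration pipeline configuration: a small sensor cohort with no
# attrition and a balanced exposure split. Unspecified values fall back to
# package defaults (see ?pipeline_config).
seed: 7
cohort:
  n_recruited: 12
  p_app_usage: 1
  p_survey_completion: 1
  p_exposure_answered: 1
  p_exposed_or_unsure: 0.5
  study_days: 7
inference:
  alpha: 0.05
  ci_quantile: 0.95
out_dir: results/demo
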