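# Demonstration pipeline configuration: simulates a small synthetic
# screening cohort, forecasts it, validates against the realized births,
# and renders the HTML report. Runs in well under a minute.
seed: 42
simulate:
  n_weeks: 120
  base_weekly_pregnancies: 110
  seasonal_amplitude: 0.1
inputs:
  pmf: synthetic-standin
coverage_threshold_pct: 55
forecast:
  n_reps: 1000
  ci_level: 0.95
  ci_method: normal
  bin_width: 2
validate:
  widths: [1, 2, 3]
report:
  title: Synthetic regional birth forecast (demo)
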