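# Full pipeline configuration for the East Java CVD screening demo.
#
# The epidemiological and economic inputs below are demonstration values:
# the published scorecard cites literature sources for the baseline event
# risk, case fatality, unit hospitalisation cost and GNI per capita
# without printing them. These stand-ins are back-solved so the demo
# reproduces the published magnitudes (about 59 trial-cohort events
# averted, 73,000 nationally, and benefit components of roughly
# US$ 333M / 192M / 192M); see the package vignette.
seed: 20170401
cohort_params:
  n_target: 12088
  p_screen: 0.91
  p_highrisk: 0.22
  p_treated_intervention: 0.80
  p_treated_control: 0.16
  sbp_mean_control: 140
  sbp_sd: 15
  treatment_effect_sbp: 13
epi_params:
  baseline_event_risk: 0.194   # cumulative 5-year CVD risk, high-risk adults
  case_fatality: 0.114         # CVD case fatality, middle-income setting
  rr_per_10: 0.80
  dw_nonfatal: 0.39
  nonfatal_duration: 1.0       # years lived with disability per survived event
  mean_age: 59
  life_expectancy: 69
  horizon: 5
econ_params:
  gni_per_capita: 3540         # USD per year
  hosp_cost_per_event: 4560    # USD per CVD hospitalisation
  indirect_fraction: 0.5
  hospitalisations_per_event: 1
cost_ledger:
  research_cost_a: 1000000
  implementation_cost_b: 328300000
  horizon: 5
  currency_label: USD
scale_factor: 1237             # national population / trial cohort (demo)
scorecard: smarthealth_scorecard.yaml
output_dir: fait-report
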