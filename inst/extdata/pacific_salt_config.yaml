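# Pipeline configuration for the Pacific salt-reduction demo: the
# epidemiological and economic parameters needed for the SROI were never
# collected, so a full run fails the readiness audit and an
# allow_partial run produces the data-gap scorecard.
seed: 20140101
cost_ledger:
  research_cost_a: 1200000
  annual_implementation_cost: 500000
  horizon: 5
  currency_label: AUD
scorecard: pacific_salt_scorecard.yaml
logic_model: pacific_salt_logic_model.yaml
output_dir: fait-report-pacific
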