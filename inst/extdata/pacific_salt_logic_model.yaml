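# Programme logic model for the Pacific salt-reduction demo.
need:
  - No baseline data on population salt intake; high burden of raised blood pressure
activities:
  - Baseline salt-intake surveys
  - Consumer awareness campaign
  - Engagement with food manufacturers and regulators
outputs:
  - National salt-intake baselines
  - Educational materials and trained health staff
  - Public-private consultations on salt policy
end_users:
  - Ministries of health
  - Food industry
  - Community health workers
anticipated_impact:
  - Reduced population salt intake and blood pressure
  - Salt commitments embedded in national food strategy
links:
  - [Baseline salt-intake surveys, National salt-intake baselines]
  - [Consumer awareness campaign, Educational materials and trained health staff]
  - [Public-private consultations on salt policy, Salt commitments embedded in national food strategy]
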