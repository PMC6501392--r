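# Impact scorecard for a community CVD screening-and-treatment programme
# in East Java, Indonesia. Canonical example of a scorecard with a
# computed SROI block (scenario benefit totals are supplied here as
# published; run_pipeline() recomputes them from parameters instead).
project_name: Community CVD screening programme, East Java
domains:
  - name: Advance knowledge
    metrics:
      - name: Peer-reviewed publications under review
        value: 2
        unit: papers
      - name: New clinical decision-support algorithms
        value: 1
        unit: algorithms
        evidence: CVD screening and treatment, calibrated to local burden of disease
    outputs:
      - Plain-language reports discussed with district and national health agencies
  - name: Capacity-building and networking
    metrics:
      - name: Local co-authors on peer-reviewed papers
        value: 5
        unit: staff
    outputs:
      - University staff and a district health official co-applicants on follow-up grants
  - name: Health systems strengthening
    metrics:
      - name: Increase in medication stock at participating facilities
        value: 50
        unit: percent
      - name: Lay health workers trained
        value: 42
        unit: staff
      - name: Nurses trained
        value: 14
        unit: staff
      - name: Doctors trained
        value: 5
        unit: staff
    outputs:
      - Electronic record created for every person screened, shared between lay workers and doctors
  - name: Health outcomes
    metrics:
      - name: People screened
        value: 11000
        unit: persons
        evidence: 91 percent of the target cohort
      - name: Screened found at high CVD risk
        value: 22
        unit: percent
      - name: High-risk on appropriate medication, intervention arm
        value: 80
        unit: percent
      - name: High-risk on appropriate medication, control arm
        value: 16
        unit: percent
      - name: Between-arm difference in mean systolic blood pressure
        value: 13
        unit: mmHg
        status: estimated
    outputs:
      - Modelling suggests 59 fewer CVD events in the intervention villages over 5 years
      - National deployment could avert roughly 73,000 CVD events over 5 years
  - name: Economic impact
    metrics:
      - name: Follow-up grant secured
        value: 70000
        unit: USD
    outputs:
      - Research-team wages contributed to the local economy
sroi:
  a: 1000000
  b: 328300000
  currency: USD
  horizon: 5
  scenarios:
    - label: conservative
      c: 717800000
    - label: base
      c: 910200000
narrative:
  need: >-
    Cardiovascular diseases are the leading cause of death globally; in
    Indonesia most people with or at high risk of CVD receive no
    appropriate treatment.
  research_response: >-
    Lay community health workers screened adults using a tablet-based
    clinical decision-support system, referred high-risk cases to doctors
    equipped with a physician-specific system, and followed patients up at
    home over twelve months in four villages.
  outcome: >-
    The first comprehensive assessment of CVD burden and access to care in
    rural Indonesia; high screening coverage, referral of high-risk cases
    and improved medicines supply and workforce skills.
  impact: >-
    Much higher use of recommended medications among high-risk individuals
    in the intervention villages, producing significant blood-pressure
    reductions; enhanced standing of the female lay health workers.
  lessons: >-
    A detailed health-systems assessment was critical context; staff
    training, medicines supply and information systems need support for
    sustainability.
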