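# Impact scorecard for a Pacific salt-reduction programme (Fiji and Samoa).
# Canonical example of a scorecard whose SROI could NOT be computed for
# lack of economic data collected during the project.
project_name: Pacific Salt Reduction Project
domains:
  - name: Advance knowledge
    metrics:
      - name: Peer-reviewed publications (direct)
        value: 7
        unit: papers
        evidence: protocol, baseline, impact and process-evaluation papers
      - name: Peer-reviewed publications (linked)
        value: 7
        unit: papers
        evidence: systematic reviews, methods and cross-cutting papers
      - name: New national datasets established
        value: 2
        unit: datasets
        evidence: population salt-level baselines for two Pacific countries
    outputs:
      - Conference presentations and researcher workshops
      - First national baselines on population salt levels in both countries
  - name: Capacity-building
    metrics:
      - name: Research higher degrees completed
        value: 3
        unit: degrees
        evidence: 1 PhD and 2 Masters
      - name: Salt-reduction training sessions for health staff
        value: 6
        unit: sessions
    outputs:
      - Pacific authors included on academic publications
      - Research assistants trained in salt-monitoring data collection
      - Staff trained in implementation science and data analysis
  - name: "Healthy eating: education, behaviour change and healthy food environments"
    metrics:
      - name: Increase in population understanding of salt harms (Samoa)
        value: 9
        unit: percentage points
        status: estimated
      - name: Reduction in people always/often adding salt to food (Samoa)
        value: 16
        unit: percentage points
        status: estimated
    outputs:
      - High campaign awareness in both countries
      - Hospital food environment changes and restaurant-grading rule on salt shakers
  - name: Engagement and networking
    metrics:
      - name: Public-private food-policy forums per year (Fiji)
        value: 2
        unit: forums
    outputs:
      - Regular face-to-face meetings with food companies
      - Multi-sectoral working groups overseeing implementation
  - name: Economic impact
    outputs:
      - Employment and spending of project funds in both economies
      - Additional lifetime income from research degrees
      - New research grant secured
sroi:
  a: 1200000
  b: 2500000
  currency: AUD
  horizon: 5
  data_gap_note: >-
    Salt-intake change could not be converted to DALYs or monetised because
    the needed epidemiological and economic parameters were not collected
    during the project. A feasible approach: model low, medium and high
    salt-intake reductions, convert to avoided hypertension-related
    morbidity over a specified period, and cost the avoided health-system
    use.
narrative:
  need: >-
    High blood pressure is widespread in Samoa and Fiji and excess salt
    intake is a key contributor, yet no accurate salt-intake data existed
    and no Pacific country had run a successful reduction campaign.
  research_response: >-
    First national baseline surveys of salt consumption in each country,
    followed by a multi-pronged campaign combining consumer education with
    engagement of food manufacturers and regulators.
  outcome: >-
    New knowledge on salt levels, demonstrated behaviour change at low
    cost, first public-private consultations on salt and health, and
    extensive training and network building.
  impact: >-
    High campaign penetration improved consumer knowledge; national food
    strategy commitments to reduce salt, fat and sugar; Pacific-specific
    salt-measurement guidance endorsed internationally.
  lessons: >-
    Three years is too short to shift mean population salt intake;
    broader food-environment change needs strong government engagement
    because voluntary industry action is unreliable.
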