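---
title: "Methods: models, parameters and design choices in fait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fait)
```

# What the package models

Assessing the impact of translational health research credibly requires
more than a publication count. `fait` implements the three components a
mixed-methods impact assessment combines:

1. a **domains-of-benefit scorecard** (Payback-style): typed metrics and
   outcome statements grouped into benefit domains such as knowledge
   advancement, capacity-building, health outcomes and economic impact;
2. a **health-economic model** that converts a measured clinical effect — a
   systolic blood-pressure (SBP) reduction in a screened high-risk cohort —
   into cardiovascular (CVD) events, deaths and disability-adjusted life
   years (DALYs) averted, monetises those gains, and reports a social
   return on investment (SROI);
3. **qualitative components**: a programme logic model, a structured case
   narrative, and a data-readiness audit that makes explicit *which*
   economic outputs cannot be computed from the data at hand.

A synthetic cohort generator stands in for individual-level trial data,
which are typically not shareable, so the whole pipeline can be exercised
and tested at desk scale.

# The health-economic model

## From blood pressure to events

The dose-response between SBP reduction and CVD events is log-linear: a
relative risk `rr_per_10` (default 0.80, from meta-analyses of
blood-pressure-lowering trials) applies per 10 mmHg of reduction, so

$$\mathrm{RR}(\Delta) = \mathrm{rr}_{10}^{\Delta/10}.$$

This form is multiplicative (`RR(a+b) = RR(a)·RR(b)`) and strictly
decreasing in Δ. Negative Δ (a harmful intervention) is rejected rather
than extrapolated: the evidence base behind the 0.80 figure concerns
reductions only.

Expected events over the horizon are a closed-form cohort expectation:

- events (control) = `n_exposed × baseline_event_risk`,
- events (intervention) = events (control) × RR(Δ),
- events averted = the difference; deaths averted = events averted ×
  `case_fatality`.

`baseline_event_risk` is defined as the **cumulative** risk over the full
horizon (default 5 years), not an annual risk that compounds; this is the
simplest reading of a fixed-horizon projection, and with the small risks
involved the two conventions differ only in the third decimal. The
closed form is verified in the test suite against an independent
per-person Bernoulli microsimulation over a grid of effect sizes, baseline
risks and case fatalities.

`n_exposed` defaults to the *intervention-arm* high-risk count when the
model is fitted from a trial summary: those are the people whose blood
pressure the programme actually lowered, and the convention that makes
"events averted in the intervention villages" the natural cohort-level
output. Extrapolation to a larger population is deliberately a bare linear
`scale_projection()` with a user-chosen factor — no age re-weighting is
attempted, because mean age and life expectancy are the only demographic
inputs the model carries.

## DALYs

DALYs averted decompose exactly into years of life lost (YLL) and years
lived with disability (YLD):

- YLL = deaths averted × `dw_fatal` × (`life_expectancy` − `mean_age`),
  with `dw_fatal = 1` (the dead state) and defaults 69 − 59 = 10 years;
- YLD = non-fatal events averted × `dw_nonfatal` × `nonfatal_duration`,
  with `dw_nonfatal = 0.39` (a weighted average of myocardial-infarction
  and moderate-to-severe stroke weights from burden-of-disease studies).

`nonfatal_duration` defaults to the YLL window (`life_expectancy −
mean_age`), mirroring the symmetric treatment of fatal and non-fatal
states; it is exposed because shorter recovery-period conventions are
common. An annual `discount_rate` (default 0 — fixed-horizon assessments
of this kind typically report undiscounted figures) replaces each duration
window `D` by the present value of a continuous unit stream,
`(1 − e^{-rD})/r`.

## Monetisation and SROI

Three benefit streams, each linear:

- **health-system savings** = events averted × hospitalisations per event
  (default 1) × unit hospitalisation cost;
- **productivity gains** = DALYs averted × `productivity_fraction` × GNI
  per capita — six months of GNI per healthy life year in the
  *conservative* scenario (fraction 0.5), twelve in the *base case* (1.0);
- **indirect benefits** = DALYs averted × `indirect_fraction` (default
  0.5) × GNI per capita.

The scenario definitions are fixed at 0.5/1.0 because that is the only
reading consistent with a published productivity range that is an exact
doubling; with the default fractions, indirect benefits equal
conservative-scenario productivity gains for identical inputs, an internal
consistency the tests assert. SROI is `c / (a + b)`: total monetised
benefit over research cost plus deployment cost. It is scale-free
(homogeneous of degree zero in a common currency rescaling), strictly
increasing in `c` and decreasing in `a` and `b`. Currencies are opaque
labels; mixing currencies is the user's responsibility, as no conversion
is performed. Internally everything is kept at full precision; rendering
rounds currency to one decimal of millions and SROI to two decimals.

A known presentation effect follows: recomputing SROI from components that
were themselves rounded to one decimal of millions (333 + 192.4 + 192.4
over 1 + 328.3) gives 2.18/2.76, while unrounded components can print as
2.19/2.77. The ±0.01–0.02 gap is a rounding residual, documented rather
than reconciled.

# The synthetic cohort generator

`generate_cohort()` emulates a two-arm community screening programme:
individual Bernoulli allocation to arm (fraction 0.5), then independent
Bernoulli draws for screening (0.91), high-risk status given screening
(0.22) and appropriate medication given high-risk (0.80 intervention /
0.16 control). SBP is normal with mean 140 mmHg and sd 15 mmHg; age is
normal (mean 59, sd 8) truncated at 18. The defaults are calibrated to a
published trial summary (about 11,000 of 12,088 screened, 22% high-risk,
80% vs 16% medication coverage, 13 mmHg between-arm SBP difference); the
SBP distribution family, its sd, and the age sd are conventions, since
trial reports rarely print them — they are parameters, not commitments.

One design choice deserves emphasis. `treatment_effect_sbp` parameterises
the **between-arm difference in mean SBP among high-risk individuals** —
the quantity screening trials report — not the per-person pharmacological
effect. Internally each treated high-risk individual (in either arm: usual
care that reaches 16% of controls is still care) has mean SBP lowered by
`treatment_effect_sbp / (p_treated_intervention − p_treated_control)`, so
the expected arm contrast equals the stated 13 mmHg exactly and
`summarize_cohort()` recovers the parameter. A positive effect therefore
requires a positive treatment-coverage gap, which the constructor
enforces. The implied per-treated effect at the defaults, 13/0.64 ≈ 20
mmHg, is at the high end of what medication alone achieves — it absorbs
the lifestyle-change component of such programmes, which the generator
does not model separately.

What the generator deliberately ignores: village-level (cluster)
randomisation — the impact model consumes only arm means, and no cluster
structure is published; follow-up-visit dynamics; and any correlation
between age, SBP and risk status. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline's estimators are consistent for
the generative model stated above, not that the model captures the
design effects of a real cluster-randomised trial.

Every cohort is generated under a mandatory seed with the caller's RNG
state saved and restored: no silent global state.

# The scorecard and qualitative components

Scorecard metrics are typed — numeric values must carry a unit, and
aggregation only ever sums within a unit (papers are never added to
datasets). A metric whose status is `not_available` carries no value: the
gap is the information, and the renderer prints it with its explanatory
note. Domain names come from a default vocabulary (knowledge, capacity,
policy, practice, population health, economic impact, plus engagement and
health-systems domains); free-text domains are accepted with a warning
because the domain list of a scorecard is deliberately flexible. No
inference is attempted about which domain a metric "really" belongs to.

A scorecard without a computed SROI block **must** carry a data-gap note —
an honest "not possible due to lack of data, here is how it could be
done" is a first-class result, not an error. The readiness audit mechanises
this: a static dependency graph maps each required parameter that has no
package default (`baseline_event_risk`, `case_fatality`,
`hosp_cost_per_event`, `gni_per_capita`, `research_cost_a`,
`implementation_cost_b`) to the outputs it blocks, so
`audit_data_readiness()` reports exactly what is missing, what it blocks
and a suggested approach. The audit is monotone: supplying a value never
grows the missing set.

The logic model keeps the five-section prospective chain (need,
activities, outputs, end-users, anticipated impact) with optional
free-form links; validation reports empty sections and dangling links
rather than throwing, because an incomplete plan is a legitimate state
while a project is being designed. Case narratives fix the five
sub-headings (need, research response, outcome, impact, lessons) and are
validated before rendering.

# Numerical and testing choices

- Tolerances: stochastic recoveries are asserted within 3 Monte-Carlo
  standard errors of the mean over 20 seeded cohorts of 12,088 persons;
  the microsimulation cross-check uses 10^4 binomial replicates of a
  10,000-person cohort per grid point. These sizes keep the full test
  suite under ten seconds while leaving the 3-SE bands tight (±0.4 mmHg
  on the SBP contrast).
- Truncation (ages at 18, SBP at 1 mmHg) is by resampling; at 5 standard
  deviations from the mean it is statistically invisible but keeps the
  stated invariants exact.
- Degenerate inputs are rejected early with named errors: empty cohorts,
  an arm with no high-risk members (the contrast is undefined), negative
  blood-pressure "reductions", `a + b = 0` denominators.
- Rendering (Markdown and a small deterministic HTML emitter) is a pure
  function of the scorecard object; byte-identical inputs give
  byte-identical documents, which the pipeline reproducibility tests rely
  on.

# Demonstration configuration

The shipped `smarthealth_config.yaml` exercises the full pipeline on a
cohort calibrated to the published screening trial. Its literature-derived
inputs (cumulative 5-year baseline event risk 0.194, case fatality 0.114,
YLD duration 1 year, GNI per capita 3,540, unit hospitalisation cost
4,560, national scale factor 1,237) are **back-solved demonstration
values**: the published assessment cites literature sources for them
without printing the numbers, so these stand-ins are chosen so the demo
reproduces the published magnitudes (≈59 trial-cohort events averted,
≈73,000 nationally, benefit components near 333/192.4/192.4 million and an
SROI pair near 2.2/2.8). They are documented here, used in examples, and
never asserted as correct values in tests — only their checkable
arithmetic relationships (the exact productivity doubling, linearity in
the unit cost, the SROI ratio arithmetic) are tested.

# Known limitations

- Single-state projection: no recurrent events, competing risks or
  multi-state disease progression.
- No uncertainty propagation: the SROI scenarios vary one valuation
  fraction; probabilistic sensitivity analysis is out of scope.
- Linear scale-up assumes the scaled population matches the trial cohort
  in risk profile and achievable coverage.
- Cluster-randomised inference is not modelled; standard errors from
  synthetic cohorts understate design effects of village-randomised
  trials.
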