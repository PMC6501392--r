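# Independent per-person Bernoulli microsimulation of the event projection.
# Each replicate draws one Bernoulli event per person (control risk p, or
# p * rr under the intervention) and one Bernoulli death per event; binomial
# draws are the exact aggregate of those per-person Bernoullis. The relative
# risk is recomputed here from the log-linear dose-response so the oracle
# shares no code path with the package.
microsim_projection <- function(n, delta_sbp, baseline_risk, case_fatality,
                                rr_per_10 = 0.80, reps = 1e4, seed = 99) {
  set.seed(seed)
  rr <- exp((delta_sbp / 10) * log(rr_per_10))
  ev_c <- rbinom(reps, n, baseline_risk)
  ev_i <- rbinom(reps, n, baseline_risk * rr)
  de_c <- rbinom(reps, ev_c, case_fatality)
  de_i <- rbinom(reps, ev_i, case_fatality)
  averted <- ev_c - ev_i
  deaths <- de_c - de_i
  list(events_averted = mean(averted),
       events_se = sd(averted) / sqrt(reps),
       deaths_averted = mean(deaths),
       deaths_se = sd(deaths) / sqrt(reps))
}

# A tiny valid scorecard built in code, for structural tests.
make_mini_scorecard <- function() {
  scorecard(
    project_name = "Mini project",
    domains = list(
      domain("Advance knowledge",
             metrics = list(metric("Publications", 3, unit = "papers"),
                            metric("Datasets", 1, unit = "datasets")),
             outputs = "A finding"),
      domain("Economic impact",
             metrics = list(metric("Grants secured", 2, unit = "grants")))
    ),
    data_gap_note = "Economic parameters not collected."
  )
}

demo_epi <- function(...) {
  epi_params(baseline_event_risk = 0.194, case_fatality = 0.3, ...)
}

demo_econ <- function(...) {
  econ_params(gni_per_capita = 3540, hosp_cost_per_event = 4560, ...)
}
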