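test_that("parameter validation rejects out-of-range inputs", {
  expect_error(cohort_params(p_screen = 1.2, seed = 1), "probability")
  expect_error(cohort_params(p_highrisk = -0.1, seed = 1), "probability")
  expect_error(cohort_params(n_target = 0, seed = 1), "positive integer")
  expect_error(cohort_params(sbp_sd = 0, seed = 1), "sbp_sd")
  expect_error(cohort_params(treatment_effect_sbp = -1, seed = 1),
               "treatment_effect_sbp")
  expect_error(cohort_params(seed = 1, p_treated_intervention = 0.1,
                             p_treated_control = 0.5),
               "between-arm contrast")
  expect_error(cohort_params(), "seed")
})

test_that("degenerate probabilities produce the implied statuses", {
  coh <- generate_cohort(cohort_params(n_target = 300, p_screen = 1,
                                       p_highrisk = 1, seed = 3))
  expect_true(all(coh$screened))
  expect_true(all(coh$high_risk))
})

test_that("cohort structure invariants hold across seeds", {
  for (s in 1:5) {
    coh <- generate_cohort(cohort_params(n_target = 1000, seed = s))
    expect_true(all(coh$screened[coh$high_risk]))   # high_risk => screened
    expect_true(all(coh$high_risk[coh$treated]))    # treated => high_risk
    expect_true(all(is.finite(coh$sbp)) && all(coh$sbp > 0))
    expect_true(all(coh$age >= 18))
    expect_setequal(unique(coh$arm), c("intervention", "control"))
  }
})

test_that("the same seed reproduces the cohort exactly and leaves global RNG alone", {
  p <- cohort_params(n_target = 500, seed = 11)
  set.seed(1234)
  before <- .Random.seed
  a <- generate_cohort(p)
  expect_identical(.Random.seed, before)
  b <- generate_cohort(p)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_params(n_target = 500, seed = 12))
  expect_false(identical(a$sbp, c2$sbp))
})

test_that("screened counts match the calibrated coverage across seeds", {
  # defaults: n_target 12088, p_screen 0.91 -> E[screened] ~ 11000
  counts <- vapply(1:10, function(s) {
    sum(generate_cohort(cohort_params(seed = s))$screened)
  }, numeric(1))
  se <- sqrt(12088 * 0.91 * 0.09 / 10)
  expect_lt(abs(mean(counts) - 12088 * 0.91), 3 * se)
})

test_that("empirical fractions converge to the parameters at large n", {
  p <- cohort_params(n_target = 100000, seed = 21)
  coh <- generate_cohort(p)
  s <- summarize_cohort(coh)
  n <- p$n_target
  expect_lt(abs(s$screening_coverage - 0.91),
            3 * sqrt(0.91 * 0.09 / n))
  expect_lt(abs(s$highrisk_fraction - 0.22),
            3 * sqrt(0.22 * 0.78 / s$n_screened))
  n_hr <- s$n_highrisk
  expect_lt(abs(s$treated_fraction_by_arm[["intervention"]] - 0.80),
            3 * sqrt(0.80 * 0.20 / n_hr[["intervention"]]))
  expect_lt(abs(s$treated_fraction_by_arm[["control"]] - 0.16),
            3 * sqrt(0.16 * 0.84 / n_hr[["control"]]))
  # mean age ~ 59 (truncation at 18 is 5 sd away, negligible)
  expect_lt(abs(mean(coh$age) - 59), 3 * 8 / sqrt(n))
})

test_that("summarize_cohort recovers the between-arm SBP contrast", {
  deltas <- vapply(1:20, function(s) {
    summarize_cohort(generate_cohort(cohort_params(seed = s)))$delta_sbp_highrisk
  }, numeric(1))
  mc_se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 13), 3 * mc_se)
})

test_that("hand-built cohorts summarise by exact arithmetic", {
  base <- data.frame(
    id = 1:4,
    arm = c("intervention", "intervention", "control", "control"),
    screened = TRUE, high_risk = TRUE, treated = FALSE,
    sbp = c(140, 136, 150, 150), age = 60)
  s <- summarize_cohort(base)
  expect_equal(s$delta_sbp_highrisk, 12.0)   # (150+150)/2 - (140+136)/2
  expect_equal(s$screening_coverage, 1)
  expect_equal(s$highrisk_fraction, 1)

  same <- base
  same$sbp <- 140
  expect_equal(summarize_cohort(same)$delta_sbp_highrisk, 0)
})

test_that("summaries fail on empty input or an arm without high-risk members", {
  expect_error(summarize_cohort(data.frame()), "non-empty")
  one_arm <- data.frame(id = 1:2, arm = c("intervention", "control"),
                        screened = TRUE, high_risk = c(TRUE, FALSE),
                        treated = FALSE, sbp = 140, age = 60)
  expect_error(summarize_cohort(one_arm), "undefined contrast.*control")
})

test_that("cohorts round-trip through CSV", {
  coh <- generate_cohort(cohort_params(n_target = 200, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$arm, coh$arm)
  expect_equal(back$treated, coh$treated)
  expect_equal(back$sbp, coh$sbp, tolerance = 1e-12)
})

test_that("simulate() generates distinct, seed-deterministic cohorts", {
  p <- cohort_params(n_target = 300, seed = 7)
  sims <- simulate(p, nsim = 3)
  expect_length(sims, 3)
  expect_identical(sims[[1]], generate_cohort(p))
  expect_false(identical(sims[[1]]$sbp, sims[[2]]$sbp))
})
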