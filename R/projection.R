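#' Epidemiological parameters for the CVD projection
#'
#' Assumptions for converting a systolic blood-pressure reduction into CVD
#' events, deaths and DALYs averted over a fixed horizon. Two parameters have
#' no defensible universal default and must be supplied: the cumulative
#' baseline event risk over the horizon and the case fatality of an event
#' (both are typically taken from the burden-of-disease literature for the
#' setting at hand).
#'
#' @param baseline_event_risk Probability an untreated cohort member suffers
#'   a CVD event (ischaemic heart disease, myocardial infarction or stroke)
#'   over the whole horizon. Cumulative, not annual.
#' @param case_fatality Probability an event is fatal.
#' @param rr_per_10 Relative risk of a CVD event per 10 mmHg systolic
#'   blood-pressure reduction; default 0.80, applied log-linearly
#'   (see [relative_risk()]).
#' @param dw_nonfatal Disability weight for life with survived CVD; default
#'   0.39 (a weighted average of myocardial-infarction and moderate-to-severe
#'   stroke weights).
#' @param dw_fatal Weight of the dead health state; 1 by convention.
#' @param mean_age Mean age of the exposed cohort, years (default 59).
#' @param life_expectancy Life expectancy used for years of life lost,
#'   years (default 69).
#' @param nonfatal_duration Years lived with disability per non-fatal event
#'   averted; defaults to `life_expectancy - mean_age`, mirroring the YLL
#'   window.
#' @param horizon Projection horizon in years (default 5).
#' @param discount_rate Annual discount rate applied to future healthy life
#'   years; default 0 (no discounting).
#'
#' @return An object of class `epi_params`.
#' @seealso [project_events()], [dalys_averted()]
#' @export
epi_params <- function(baseline_event_risk,
                       case_fatality,
                       rr_per_10 = 0.80,
                       dw_nonfatal = 0.39,
                       dw_fatal = 1.0,
                       mean_age = 59,
                       life_expectancy = 69,
                       nonfatal_duration = NULL,
                       horizon = 5,
                       discount_rate = 0) {
  if (is.null(nonfatal_duration)) {
    nonfatal_duration <- life_expectancy - mean_age
  }
  p <- list(baseline_event_risk = baseline_event_risk,
            case_fatality = case_fatality, rr_per_10 = rr_per_10,
            dw_nonfatal = dw_nonfatal, dw_fatal = dw_fatal,
            mean_age = mean_age, life_expectancy = life_expectancy,
            nonfatal_duration = nonfatal_duration, horizon = horizon,
            discount_rate = discount_rate)
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(is.numeric(p$rr_per_10) && p$rr_per_10 > 0 && p$rr_per_10 <= 1,
      "`rr_per_10` must lie in (0, 1]")
  chk(is.numeric(p$baseline_event_risk) &&
        p$baseline_event_risk >= 0 && p$baseline_event_risk <= 1,
      "`baseline_event_risk` must be a probability in [0, 1]")
  chk(is.numeric(p$case_fatality) &&
        p$case_fatality >= 0 && p$case_fatality <= 1,
      "`case_fatality` must be a probability in [0, 1]")
  chk(p$dw_nonfatal >= 0 && p$dw_nonfatal <= p$dw_fatal && p$dw_fatal <= 1,
      "disability weights must satisfy 0 <= dw_nonfatal <= dw_fatal <= 1")
  chk(p$life_expectancy >= p$mean_age,
      "`life_expectancy` must be >= `mean_age`")
  chk(p$nonfatal_duration >= 0, "`nonfatal_duration` must be >= 0")
  chk(p$horizon > 0, "`horizon` must be > 0")
  chk(p$discount_rate >= 0, "`discount_rate` must be >= 0")
  structure(p, class = "epi_params")
}

#' Relative risk of a CVD event for a blood-pressure reduction
#'
#' Applies the log-linear dose-response: a relative risk of `rr_per_10` for
#' every 10 mmHg of systolic blood-pressure reduction, i.e.
#' `rr_per_10^(delta_sbp / 10)`. Blood-pressure *increases* (negative
#' `delta_sbp`) are outside the model and rejected rather than extrapolated.
#'
#' @param delta_sbp Systolic blood-pressure reduction, mmHg (>= 0; may be a
#'   vector).
#' @param rr_per_10 Relative risk per 10 mmHg, in (0, 1].
#' @return Relative risk(s) in (0, 1].
#' @examples
#' relative_risk(10)          # 0.80
#' relative_risk(13)          # ~0.748
#' @export
relative_risk <- function(delta_sbp, rr_per_10 = 0.80) {
  if (!is.numeric(rr_per_10) || length(rr_per_10) != 1L ||
      rr_per_10 <= 0 || rr_per_10 > 1) {
    stop("`rr_per_10` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(delta_sbp) || anyNA(delta_sbp) || any(delta_sbp < 0)) {
    stop("`delta_sbp` must be >= 0: blood-pressure increases are outside the model",
         call. = FALSE)
  }
  rr_per_10^(delta_sbp / 10)
}

#' Project CVD events, deaths and DALYs averted
#'
#' `project_events()` computes the closed-form cohort expectation: the
#' control arm experiences `n_exposed * baseline_event_risk` events over the
#' horizon; the intervention arm the same scaled by
#' [relative_risk()] of the achieved blood-pressure reduction; deaths averted
#' are events averted times the case fatality. Values are expectations and
#' need not be integers. `dalys_averted()` then fills in years of life lost
#' (deaths averted x `dw_fatal` x remaining life expectancy), years lived
#' with disability (non-fatal events averted x `dw_nonfatal` x
#' `nonfatal_duration`) and their sum, the DALYs averted (healthy life years
#' gained). With a positive `discount_rate` the two duration windows are
#' replaced by the present value of a continuous unit stream,
#' `(1 - exp(-r * D)) / r`.
#'
#' @param n_exposed Number of persons exposed to the blood-pressure
#'   reduction (>= 0).
#' @param delta_sbp Achieved systolic blood-pressure reduction, mmHg (>= 0).
#' @param params An [epi_params()] object.
#' @return An object of class `event_projection`: a list with `n_exposed`,
#'   `delta_sbp`, `rr_applied`, `events_control`, `events_intervention`,
#'   `events_averted`, `deaths_averted`, and (after `dalys_averted()`)
#'   `yll_averted`, `yld_averted`, `dalys_averted`.
#' @examples
#' ep <- epi_params(baseline_event_risk = 0.10, case_fatality = 0.3)
#' pr <- dalys_averted(project_events(1000, 10, ep), ep)
#' pr
#' @export
project_events <- function(n_exposed, delta_sbp, params) {
  if (!inherits(params, "epi_params")) {
    stop("`params` must be an `epi_params` object", call. = FALSE)
  }
  if (!is.numeric(n_exposed) || length(n_exposed) != 1L || n_exposed < 0) {
    stop("`n_exposed` must be a single non-negative number", call. = FALSE)
  }
  rr <- relative_risk(delta_sbp, params$rr_per_10)
  events_control <- n_exposed * params$baseline_event_risk
  events_intervention <- events_control * rr
  events_averted <- events_control - events_intervention
  structure(list(
    n_exposed = n_exposed,
    delta_sbp = delta_sbp,
    rr_applied = rr,
    events_control = events_control,
    events_intervention = events_intervention,
    events_averted = events_averted,
    deaths_averted = events_averted * params$case_fatality,
    yll_averted = NA_real_,
    yld_averted = NA_real_,
    dalys_averted = NA_real_
  ), class = "event_projection")
}

# Present value of a continuous unit stream over `years` at rate `r`.
discounted_years <- function(years, r) {
  if (r <= 0) years else (1 - exp(-r * years)) / r
}

#' @rdname project_events
#' @param projection An `event_projection` from `project_events()`.
#' @export
dalys_averted <- function(projection, params) {
  if (!inherits(projection, "event_projection")) {
    stop("`projection` must come from `project_events()`", call. = FALSE)
  }
  if (!inherits(params, "epi_params")) {
    stop("`params` must be an `epi_params` object", call. = FALSE)
  }
  yll_window <- discounted_years(params$life_expectancy - params$mean_age,
                                 params$discount_rate)
  yld_window <- discounted_years(params$nonfatal_duration,
                                 params$discount_rate)
  projection$yll_averted <- projection$deaths_averted * params$dw_fatal *
    yll_window
  projection$yld_averted <-
    (projection$events_averted - projection$deaths_averted) *
    params$dw_nonfatal * yld_window
  projection$dalys_averted <- projection$yll_averted + projection$yld_averted
  projection
}

#' Linearly scale a projection to a larger population
#'
#' Multiplies every expectation-scale field (persons, events, deaths, life
#' years) by `scale_factor`, leaving the blood-pressure reduction and the
#' relative risk untouched. This is the mechanism for "if deployed
#' nationally" extrapolations: the user supplies the ratio of the target
#' population to the cohort.
#'
#' @param projection An `event_projection`.
#' @param scale_factor Non-negative multiplier.
#' @return The scaled `event_projection`.
#' @export
scale_projection <- function(projection, scale_factor) {
  if (!inherits(projection, "event_projection")) {
    stop("`projection` must be an `event_projection`", call. = FALSE)
  }
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      is.na(scale_factor) || scale_factor < 0) {
    stop("`scale_factor` must be a single non-negative number", call. = FALSE)
  }
  for (fld in c("n_exposed", "events_control", "events_intervention",
                "events_averted", "deaths_averted", "yll_averted",
                "yld_averted", "dalys_averted")) {
    projection[[fld]] <- projection[[fld]] * scale_factor
  }
  projection
}

#' @export
print.event_projection <- function(x, digits = 1, ...) {
  cat("CVD event projection\n")
  cat(sprintf("  exposed: %s persons; SBP reduction %.1f mmHg (RR %.4f)\n",
              format(round(x$n_exposed), big.mark = ","),
              x$delta_sbp, x$rr_applied))
  cat(sprintf("  events: %.*f (control) vs %.*f (intervention) -> %.*f averted\n",
              digits, x$events_control, digits, x$events_intervention,
              digits, x$events_averted))
  cat(sprintf("  deaths averted: %.*f\n", digits, x$deaths_averted))
  if (!is.na(x$dalys_averted)) {
    cat(sprintf("  DALYs averted: %.*f (YLL %.*f + YLD %.*f)\n",
                digits, x$dalys_averted, digits, x$yll_averted,
                digits, x$yld_averted))
  } else {
    cat("  DALYs: not yet computed (call dalys_averted())\n")
  }
  invisible(x)
}
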