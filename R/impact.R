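#' Fit the full health-economic impact model
#'
#' The central modelling function: takes the achieved blood-pressure
#' reduction (either directly or from a [summarize_cohort()] trial summary),
#' projects CVD events, deaths and DALYs averted over the horizon,
#' optionally scales the projection to a larger population, monetises the
#' gains and — when a [cost_ledger()] is supplied — computes the social
#' return on investment under the conservative and base-case scenarios.
#'
#' @param x Either a `trial_summary` (the blood-pressure contrast and the
#'   exposed count are taken from it) or a single non-negative number, the
#'   systolic blood-pressure reduction in mmHg.
#' @param epi An [epi_params()] object.
#' @param econ An [econ_params()] object, or `NULL` to stop after the
#'   health projection.
#' @param ledger Optional [cost_ledger()]; enables the SROI scenarios.
#' @param n_exposed Persons exposed to the reduction. Defaults to the
#'   intervention-arm high-risk count when `x` is a trial summary (those are
#'   the people whose blood pressure the programme lowered); required
#'   otherwise.
#' @param scale_factor Linear scale-up factor applied to the projection
#'   before monetisation (default 1, i.e. the trial cohort itself).
#' @param custom_fractions Extra productivity fractions passed to
#'   [run_scenarios()].
#' @return An object of class `fait_impact` with components `projection`
#'   (an `event_projection` with DALYs), `benefits` (conservative-scenario
#'   `benefit_components`, if `econ` given), `scenarios` (an
#'   `sroi_scenarios` list, if `ledger` given) and the inputs.
#' @examples
#' ep <- epi_params(baseline_event_risk = 0.194, case_fatality = 0.3)
#' ec <- econ_params(gni_per_capita = 3540, hosp_cost_per_event = 4560)
#' led <- cost_ledger(1e6, 328.3e6)
#' fit <- fait_impact(13, epi = ep, econ = ec, ledger = led,
#'                    n_exposed = 1210)
#' summary(fit)
#' @export
fait_impact <- function(x, epi, econ = NULL, ledger = NULL,
                        n_exposed = NULL, scale_factor = 1,
                        custom_fractions = NULL) {
  if (inherits(x, "trial_summary")) {
    delta <- max(x$delta_sbp_highrisk, 0)
    if (is.null(n_exposed)) n_exposed <- x$n_highrisk[["intervention"]]
  } else {
    delta <- x
    if (is.null(n_exposed)) {
      stop("`n_exposed` is required when `x` is not a trial summary",
           call. = FALSE)
    }
  }
  proj <- dalys_averted(project_events(n_exposed, delta, epi), epi)
  proj <- scale_projection(proj, scale_factor)
  benefits <- NULL
  scenarios <- NULL
  if (!is.null(econ)) {
    benefits <- assemble_benefits(proj, econ, scenario_label = "conservative")
    if (!is.null(ledger)) {
      scenarios <- run_scenarios(proj, econ, ledger,
                                 custom_fractions = custom_fractions)
    }
  }
  structure(list(projection = proj, benefits = benefits,
                 scenarios = scenarios, epi = epi, econ = econ,
                 ledger = ledger, scale_factor = scale_factor),
            class = "fait_impact")
}

#' @export
print.fait_impact <- function(x, ...) {
  cat("FAIT health-economic impact model\n\n")
  print(x$projection)
  if (!is.null(x$scenarios)) {
    cat("\n")
    print(x$scenarios)
  } else if (!is.null(x$benefits)) {
    cat("\n")
    print(x$benefits)
  }
  invisible(x)
}

#' @export
summary.fait_impact <- function(object, ...) {
  structure(object, class = c("summary.fait_impact", class(object)))
}

#' @export
print.summary.fait_impact <- function(x, ...) {
  print.fait_impact(x, ...)
  pr <- x$projection
  if (!is.null(x$benefits)) {
    cat(sprintf("\nPer event averted: %s in hospitalisation savings\n",
                format_currency(x$econ$hosp_cost_per_event *
                                  x$econ$hospitalisations_per_event)))
  }
  if (x$scale_factor != 1) {
    cat(sprintf("Projection scaled by %.1f relative to the trial cohort\n",
                x$scale_factor))
  }
  cat(sprintf("DALY split: %.1f%% years of life lost, %.1f%% years lived with disability\n",
              100 * pr$yll_averted / pr$dalys_averted,
              100 * pr$yld_averted / pr$dalys_averted))
  invisible(x)
}

#' Plot benefit components by scenario
#'
#' Stacked barplot of the three monetised benefit streams for each SROI
#' scenario, with the total cost `a + b` drawn as a reference line: bars
#' above the line correspond to SROI > 1.
#'
#' @param x A `fait_impact` object fitted with economic parameters and a
#'   cost ledger.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of component values that was plotted.
#' @export
plot.fait_impact <- function(x, ...) {
  if (is.null(x$scenarios)) {
    stop("nothing to plot: fit with `econ` and `ledger` to get scenarios",
         call. = FALSE)
  }
  comp <- vapply(x$scenarios, function(r) {
    b <- attr(r, "benefits")
    c(health_system = b$health_system_savings,
      productivity = b$productivity_gain,
      indirect = b$indirect_benefit)
  }, numeric(3))
  bp <- graphics::barplot(comp / 1e6, legend.text = rownames(comp),
                          ylab = "Benefit (millions)",
                          xlab = "Scenario", ...)
  denom <- (x$ledger$research_cost_a + x$ledger$implementation_cost_b) / 1e6
  graphics::abline(h = denom, lty = 2)
  graphics::mtext(sprintf("total cost a + b = %.1fM", denom),
                  side = 4, at = denom, las = 1, cex = 0.7)
  invisible(comp)
}
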