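#' Cost ledger: the a and b of the SROI denominator
#'
#' Records the cost of the research itself (`a`) and the cost of using or
#' deploying the research outcomes at scale (`b`). `b` may be given directly
#' or as an annual deployment cost times the horizon. Currencies are opaque
#' labels: no conversion is performed, so `a`, `b` and the benefits must be
#' expressed in the same currency.
#'
#' @param research_cost_a Total research project cost.
#' @param implementation_cost_b Total cost of deploying the trialled
#'   intervention over the horizon. Optional if
#'   `annual_implementation_cost` is given.
#' @param annual_implementation_cost Optional annual deployment cost; when
#'   supplied, `implementation_cost_b` defaults to
#'   `annual_implementation_cost * horizon` and, if also given explicitly,
#'   must equal it.
#' @param horizon Years over which costs (and benefits) accrue; default 5.
#' @param currency_label Currency tag, e.g. `"USD"`; informational only.
#' @return An object of class `cost_ledger`.
#' @examples
#' cost_ledger(1e6, 328.3e6, currency_label = "USD")
#' cost_ledger(0.5e6 * 2.4, annual_implementation_cost = 5e5, horizon = 5)
#' @export
cost_ledger <- function(research_cost_a,
                        implementation_cost_b = NULL,
                        annual_implementation_cost = NULL,
                        horizon = 5,
                        currency_label = "USD") {
  if (is.null(implementation_cost_b)) {
    if (is.null(annual_implementation_cost)) {
      stop("supply `implementation_cost_b` or `annual_implementation_cost`",
           call. = FALSE)
    }
    implementation_cost_b <- project_cost(annual_implementation_cost, horizon)
  } else if (!is.null(annual_implementation_cost)) {
    expected <- project_cost(annual_implementation_cost, horizon)
    if (!isTRUE(all.equal(implementation_cost_b, expected))) {
      stop("`implementation_cost_b` must equal annual cost x horizon when both are given",
           call. = FALSE)
    }
  }
  if (research_cost_a < 0 || implementation_cost_b < 0) {
    stop("costs must be >= 0", call. = FALSE)
  }
  structure(list(research_cost_a = research_cost_a,
                 implementation_cost_b = implementation_cost_b,
                 annual_implementation_cost = annual_implementation_cost,
                 horizon = horizon,
                 currency_label = currency_label),
            class = "cost_ledger")
}

#' Project an annual cost over a number of years
#'
#' Simple undiscounted multiplication, the convention used for deployment
#' cost projections in the scorecards.
#'
#' @param annual_cost Cost per year (>= 0).
#' @param years Number of years (>= 0).
#' @return `annual_cost * years`.
#' @examples
#' project_cost(500000, 5)  # 2.5 million
#' @export
project_cost <- function(annual_cost, years) {
  if (annual_cost < 0 || years < 0) {
    stop("`annual_cost` and `years` must be >= 0", call. = FALSE)
  }
  annual_cost * years
}

#' Economic valuation parameters
#'
#' Parameters that monetise the projected health gains: the average cost of
#' a CVD hospitalisation (with a fixed number of hospitalisations per
#' event), and per-capita Gross National Income (GNI) as the wage proxy
#' attached to each healthy life year gained. Productivity gains are valued
#' at `productivity_fraction` of a year's GNI per healthy life year — 0.5
#' (six months) in the conservative scenario, 1.0 (twelve months) in the
#' base case — and indirect, non-medical benefits at `indirect_fraction`
#' (default one half) of GNI per healthy life year.
#'
#' @param gni_per_capita GNI per capita per year.
#' @param hosp_cost_per_event Average cost of a hospitalisation for a CVD
#'   event.
#' @param productivity_fraction Fraction of a year's GNI credited as
#'   productivity per healthy life year gained, in \[0, 1\].
#' @param indirect_fraction Fraction of GNI credited as indirect benefit per
#'   healthy life year gained; default 0.5.
#' @param hospitalisations_per_event Hospitalisations per CVD event;
#'   default 1.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(gni_per_capita,
                        hosp_cost_per_event,
                        productivity_fraction = 0.5,
                        indirect_fraction = 0.5,
                        hospitalisations_per_event = 1) {
  p <- list(gni_per_capita = gni_per_capita,
            hosp_cost_per_event = hosp_cost_per_event,
            productivity_fraction = productivity_fraction,
            indirect_fraction = indirect_fraction,
            hospitalisations_per_event = hospitalisations_per_event)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                   is.na(v) || v < 0, logical(1)))) {
    stop("all economic parameters must be single non-negative numbers",
         call. = FALSE)
  }
  if (p$productivity_fraction > 1) {
    stop("`productivity_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "econ_params")
}

#' Benefit components: monetising the projection
#'
#' The three benefit streams of the economic model, each linear in the
#' projected health gains:
#' * `health_system_savings()`: events averted x hospitalisations per event
#'   x unit hospitalisation cost;
#' * `productivity_gain()`: healthy life years (DALYs averted) x
#'   `productivity_fraction` x GNI per capita;
#' * `indirect_benefit()`: healthy life years x `indirect_fraction` x GNI
#'   per capita.
#'
#' `assemble_benefits()` evaluates all three for an [project_events()]
#' projection (DALYs must already be filled in via [dalys_averted()]) and
#' returns them with their total, the `c` of the SROI numerator.
#'
#' @param events_averted Expected CVD events averted (>= 0).
#' @param dalys_averted Healthy life years gained (>= 0).
#' @param params An [econ_params()] object.
#' @param projection An `event_projection` with DALYs computed.
#' @param scenario_label Label recorded on the output
#'   (`"conservative"`, `"base"` or `"custom"`).
#' @return `assemble_benefits()` returns an object of class
#'   `benefit_components` with `health_system_savings`, `productivity_gain`,
#'   `indirect_benefit`, `total_c` and `scenario_label`; the three helpers
#'   return plain currency amounts.
#' @examples
#' ec <- econ_params(gni_per_capita = 3540, hosp_cost_per_event = 4560)
#' health_system_savings(100, ec)
#' productivity_gain(10, ec)
#' @export
health_system_savings <- function(events_averted, params) {
  stopifnot(inherits(params, "econ_params"))
  if (events_averted < 0) stop("`events_averted` must be >= 0", call. = FALSE)
  events_averted * params$hospitalisations_per_event *
    params$hosp_cost_per_event
}

#' @rdname health_system_savings
#' @export
productivity_gain <- function(dalys_averted, params) {
  stopifnot(inherits(params, "econ_params"))
  if (dalys_averted < 0) stop("`dalys_averted` must be >= 0", call. = FALSE)
  dalys_averted * params$productivity_fraction * params$gni_per_capita
}

#' @rdname health_system_savings
#' @export
indirect_benefit <- function(dalys_averted, params) {
  stopifnot(inherits(params, "econ_params"))
  if (dalys_averted < 0) stop("`dalys_averted` must be >= 0", call. = FALSE)
  dalys_averted * params$indirect_fraction * params$gni_per_capita
}

#' @rdname health_system_savings
#' @export
assemble_benefits <- function(projection, params, scenario_label = "custom") {
  stopifnot(inherits(projection, "event_projection"),
            inherits(params, "econ_params"))
  if (is.na(projection$dalys_averted)) {
    stop("projection has no DALYs: call `dalys_averted()` first",
         call. = FALSE)
  }
  hs <- health_system_savings(projection$events_averted, params)
  pg <- productivity_gain(projection$dalys_averted, params)
  ib <- indirect_benefit(projection$dalys_averted, params)
  structure(list(health_system_savings = hs,
                 productivity_gain = pg,
                 indirect_benefit = ib,
                 total_c = hs + pg + ib,
                 scenario_label = scenario_label),
            class = "benefit_components")
}

#' @export
print.benefit_components <- function(x, ...) {
  cat(sprintf("Benefit components (%s scenario)\n", x$scenario_label))
  cat(sprintf("  health-system savings: %s\n", format_currency(x$health_system_savings)))
  cat(sprintf("  productivity gains:    %s\n", format_currency(x$productivity_gain)))
  cat(sprintf("  indirect benefits:     %s\n", format_currency(x$indirect_benefit)))
  cat(sprintf("  total (c):             %s\n", format_currency(x$total_c)))
  invisible(x)
}

# Currency amounts rendered to one decimal of millions, matching the
# scorecard convention; small amounts printed plainly.
format_currency <- function(x, label = NULL) {
  s <- if (abs(x) >= 1e5) sprintf("%.1f million", x / 1e6) else {
    format(round(x, 2), big.mark = ",", scientific = FALSE)
  }
  if (is.null(label)) s else paste(label, s)
}

#' Social return on investment
#'
#' The SROI ratio `c / (a + b)`: total monetised benefit over the sum of the
#' research cost and the cost of deploying the research outcomes.
#'
#' @param c Total benefit (currency, >= 0), e.g. `total_c` from
#'   [assemble_benefits()], or a `benefit_components` object.
#' @param ledger A [cost_ledger()].
#' @param scenario_label Label recorded on the result.
#' @return An object of class `sroi_result` with `sroi`, `a`, `b`, `c` and
#'   `scenario_label`.
#' @examples
#' sroi(717.8e6, cost_ledger(1e6, 328.3e6))
#' @export
sroi <- function(c, ledger, scenario_label = NULL) {
  stopifnot(inherits(ledger, "cost_ledger"))
  if (inherits(c, "benefit_components")) {
    if (is.null(scenario_label)) scenario_label <- c$scenario_label
    c <- c$total_c
  }
  if (is.null(scenario_label)) scenario_label <- "custom"
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0) {
    stop("`c` must be a single non-negative benefit amount", call. = FALSE)
  }
  denom <- ledger$research_cost_a + ledger$implementation_cost_b
  if (denom <= 0) {
    stop("SROI undefined: total cost a + b must be > 0", call. = FALSE)
  }
  structure(list(sroi = c / denom,
                 a = ledger$research_cost_a,
                 b = ledger$implementation_cost_b,
                 c = c,
                 currency_label = ledger$currency_label,
                 scenario_label = scenario_label),
            class = "sroi_result")
}

#' @export
print.sroi_result <- function(x, ...) {
  cat(sprintf("SROI (%s): %.2f  [c = %s; a = %s; b = %s; %s]\n",
              x$scenario_label, x$sroi, format_currency(x$c),
              format_currency(x$a), format_currency(x$b), x$currency_label))
  invisible(x)
}

#' Run the conservative and base-case SROI scenarios
#'
#' Evaluates the benefit components and the SROI ratio under the
#' conservative scenario (productivity valued at six months of GNI per
#' healthy life year, `productivity_fraction = 0.5`) and the base case
#' (twelve months, `1.0`), plus any user-supplied custom fractions. The
#' conservative SROI is never above the base-case SROI.
#'
#' @param projection An `event_projection` with DALYs computed
#'   ([dalys_averted()]).
#' @param params An [econ_params()] object; its `productivity_fraction` is
#'   overridden per scenario.
#' @param ledger A [cost_ledger()].
#' @param custom_fractions Optional named numeric vector of extra
#'   productivity fractions, e.g. `c(mid = 0.75)`.
#' @return A list of class `sroi_scenarios`: one [sroi()] result per
#'   scenario, each with the matching `benefit_components` attached as
#'   attribute `"benefits"`.
#' @export
run_scenarios <- function(projection, params, ledger,
                          custom_fractions = NULL) {
  fractions <- c(conservative = 0.5, base = 1.0, custom_fractions)
  out <- lapply(seq_along(fractions), function(i) {
    p <- params
    p$productivity_fraction <- fractions[[i]]
    ben <- assemble_benefits(projection, p,
                             scenario_label = names(fractions)[i])
    res <- sroi(ben, ledger)
    attr(res, "benefits") <- ben
    res
  })
  names(out) <- names(fractions)
  structure(out, class = "sroi_scenarios")
}

#' @export
print.sroi_scenarios <- function(x, ...) {
  cat("Social return on investment scenarios\n")
  for (r in x) {
    cat(sprintf("  %-14s %.2f  (c = %s)\n",
                paste0(r$scenario_label, ":"), r$sroi, format_currency(r$c)))
  }
  invisible(x)
}
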