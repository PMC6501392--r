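#' Programme logic model
#'
#' The prospective planning chain of an impact assessment: the need or issue
#' the research addresses, the activities undertaken, their expected
#' outputs, the end-users of those outputs and the anticipated impact.
#' Optional `links` record free-form arrows between named elements (e.g.
#' from an activity to an output); no layout semantics are imposed.
#'
#' The constructor is permissive — completeness is the business of
#' [validate_logic_model()], which reports findings instead of throwing, so
#' that a half-built model can be inspected while a project is being
#' planned.
#'
#' @param need Text describing the need or issue.
#' @param activities,outputs,end_users,anticipated_impact Character vectors.
#' @param links List of length-2 character vectors `c(from, to)`; each side
#'   must match an element of one of the five sections.
#' @return An object of class `logic_model`.
#' @export
logic_model <- function(need = character(), activities = character(),
                        outputs = character(), end_users = character(),
                        anticipated_impact = character(), links = list()) {
  as_chr <- function(x) {
    x <- as.character(unlist(x, use.names = FALSE))
    x[nzchar(trimws(x))]
  }
  links <- lapply(links, function(l) {
    l <- as.character(unlist(l, use.names = FALSE))
    if (length(l) != 2L) {
      stop("each link must be a (from, to) pair", call. = FALSE)
    }
    l
  })
  structure(list(need = as_chr(need), activities = as_chr(activities),
                 outputs = as_chr(outputs), end_users = as_chr(end_users),
                 anticipated_impact = as_chr(anticipated_impact),
                 links = links),
            class = "logic_model")
}

logic_sections <- c("need", "activities", "outputs", "end_users",
                    "anticipated_impact")

#' Validate a programme logic model
#'
#' Checks completeness (all five sections non-empty) and link integrity
#' (every link endpoint names an existing element). Validation returns its
#' findings rather than throwing: content problems are results, not errors.
#'
#' @param model A [logic_model()].
#' @return A list of class `logic_validation` with `valid` (logical),
#'   `empty_sections` (character) and `dangling_links` (list of offending
#'   pairs).
#' @export
validate_logic_model <- function(model) {
  stopifnot(inherits(model, "logic_model"))
  empty <- logic_sections[vapply(logic_sections,
                                 function(s) length(model[[s]]) == 0L,
                                 logical(1))]
  elements <- unlist(model[logic_sections], use.names = FALSE)
  dangling <- Filter(function(l) !all(l %in% elements), model$links)
  structure(list(valid = length(empty) == 0L && length(dangling) == 0L,
                 empty_sections = empty,
                 dangling_links = dangling),
            class = "logic_validation")
}

#' @export
print.logic_validation <- function(x, ...) {
  if (x$valid) {
    cat("Logic model valid: all five sections populated, all links resolve\n")
  } else {
    if (length(x$empty_sections)) {
      cat("Empty sections:", paste(x$empty_sections, collapse = ", "), "\n")
    }
    for (l in x$dangling_links) {
      cat(sprintf("Dangling link: '%s' -> '%s'\n", l[1], l[2]))
    }
  }
  invisible(x)
}

#' Structured case-study narrative
#'
#' A short account of how translation occurred and how impact was
#' generated, structured around the five standard sub-headings: need,
#' research response, outcome, impact and lessons. All five are required
#' and must be non-empty.
#'
#' @param need,research_response,outcome,impact,lessons Text for each
#'   sub-heading.
#' @return An object of class `case_narrative`.
#' @export
case_narrative <- function(need, research_response, outcome, impact,
                           lessons) {
  n <- list(need = need, research_response = research_response,
            outcome = outcome, impact = impact, lessons = lessons)
  bad <- names(n)[vapply(n, function(v) is.null(v) || !is.character(v) ||
                           length(v) != 1L || !nzchar(trimws(v)),
                         logical(1))]
  if (length(bad)) {
    stop("case narrative section(s) missing or empty: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(n, class = "case_narrative")
}

narrative_headings <- c(need = "Need",
                        research_response = "Research response",
                        outcome = "Outcome",
                        impact = "Impact",
                        lessons = "Lessons")

#' Render a case narrative
#'
#' Deterministic rendering with the five sub-headings in canonical order
#' (need, research response, outcome, impact, lessons). The narrative is
#' re-validated first so a hand-edited object with an emptied section fails
#' loudly, naming the section.
#'
#' @param narrative A [case_narrative()].
#' @param format `"markdown"` or `"html"`.
#' @return The rendered document as one string.
#' @export
render_narrative <- function(narrative, format = c("markdown", "html")) {
  format <- match.arg(format)
  if (!inherits(narrative, "case_narrative")) {
    stop("`narrative` must be a case_narrative()", call. = FALSE)
  }
  do.call(case_narrative, unclass(narrative)[names(narrative_headings)])
  md <- unlist(lapply(names(narrative_headings), function(k) {
    c(sprintf("### %s", narrative_headings[[k]]), "", narrative[[k]], "")
  }))
  doc <- paste(md, collapse = "\n")
  if (format == "html") markdown_to_html(doc) else doc
}

# Static dependency graph from required configuration fields to the
# pipeline outputs they unlock. Fields with package defaults never appear:
# only parameters that must come from data or the literature can block an
# output.
readiness_requirements <- function() {
  list(
    epi_params = list(
      baseline_event_risk = list(
        outputs = c("events averted", "deaths averted", "DALYs averted",
                    "health_system_savings", "productivity_gain",
                    "indirect_benefit", "total benefit (c)", "SROI"),
        approach = paste("Obtain a cumulative CVD event risk over the",
                         "horizon for the untreated cohort from local",
                         "burden-of-disease data or the literature.")),
      case_fatality = list(
        outputs = c("deaths averted", "DALYs averted", "productivity_gain",
                    "indirect_benefit", "total benefit (c)", "SROI"),
        approach = paste("Use published CVD case-fatality rates for a",
                         "comparable (e.g. middle-income) setting."))
    ),
    econ_params = list(
      hosp_cost_per_event = list(
        outputs = c("health_system_savings", "total benefit (c)", "SROI"),
        approach = paste("Cost the average CVD hospitalisation from",
                         "national tariffs or hospital billing data.")),
      gni_per_capita = list(
        outputs = c("productivity_gain", "indirect_benefit",
                    "total benefit (c)", "SROI"),
        approach = paste("Take per-capita Gross National Income from",
                         "national accounts (World Bank series)."))
    ),
    cost_ledger = list(
      research_cost_a = list(
        outputs = "SROI",
        approach = "Total the research project budget from grant records."),
      implementation_cost_b = list(
        outputs = "SROI",
        approach = paste("Cost the at-scale deployment of the trialled",
                         "intervention (staffing, consumables, drugs),",
                         "or supply an annual cost and horizon."))
    )
  )
}

field_present <- function(section, field, cfg) {
  v <- cfg[[section]][[field]]
  if (!is.null(v)) return(is.numeric(v) && !anyNA(v))
  # b can be derived from an annual cost and a horizon
  if (section == "cost_ledger" && field == "implementation_cost_b") {
    a <- cfg$cost_ledger$annual_implementation_cost
    h <- cfg$cost_ledger$horizon
    return(!is.null(a) && !is.null(h) && is.numeric(a) && is.numeric(h))
  }
  FALSE
}

#' Audit whether a configuration can support the quantitative pipeline
#'
#' Walks the static dependency graph from required epidemiological,
#' economic and cost parameters to the outputs they unlock, and reports
#' every required field absent from `config` together with the downstream
#' outputs it blocks and a suggested approach for obtaining it. A complete
#' configuration yields an empty report. The audit is monotone: adding a
#' value never grows the missing list.
#'
#' @param config A named list (typically a parsed pipeline config) with
#'   sections `epi_params`, `econ_params` and `cost_ledger`; values may be
#'   absent.
#' @return An object of class `readiness_report` with `missing_fields`,
#'   `affected_outputs` (union over missing fields) and
#'   `suggested_approach` (named character vector).
#' @examples
#' audit_data_readiness(list(epi_params = list(baseline_event_risk = 0.1,
#'                                             case_fatality = 0.3)))
#' @export
audit_data_readiness <- function(config) {
  if (!is.list(config)) stop("`config` must be a list", call. = FALSE)
  reqs <- readiness_requirements()
  missing_fields <- character()
  affected <- character()
  approaches <- character()
  for (section in names(reqs)) {
    for (field in names(reqs[[section]])) {
      if (!field_present(section, field, config)) {
        missing_fields <- c(missing_fields, field)
        affected <- c(affected, reqs[[section]][[field]]$outputs)
        approaches[field] <- reqs[[section]][[field]]$approach
      }
    }
  }
  structure(list(missing_fields = missing_fields,
                 affected_outputs = unique(affected),
                 suggested_approach = approaches),
            class = "readiness_report")
}

#' @export
print.readiness_report <- function(x, ...) {
  if (!length(x$missing_fields)) {
    cat("Data readiness: complete — all quantitative outputs computable\n")
  } else {
    cat("Data readiness: incomplete\n")
    for (f in x$missing_fields) {
      cat(sprintf("  missing `%s` — %s\n", f, x$suggested_approach[[f]]))
    }
    cat("  blocked outputs:", paste(x$affected_outputs, collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' @rdname audit_data_readiness
#' @param x A `readiness_report`.
#' @return `is_ready()` returns `TRUE` when nothing is missing.
#' @export
is_ready <- function(x) {
  stopifnot(inherits(x, "readiness_report"))
  length(x$missing_fields) == 0L
}
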