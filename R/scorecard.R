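#' Default domains-of-benefit vocabulary
#'
#' The controlled vocabulary for scorecard domains: knowledge generation,
#' capacity-building, policy, clinical practice / health services,
#' population health and economic benefit, plus the engagement and
#' health-systems domains that community-level projects typically add.
#' Domains outside the vocabulary are accepted with a warning — the domain
#' list is deliberately flexible.
#'
#' @return Character vector of domain names.
#' @export
fait_domains <- function() {
  c("Advance knowledge",
    "Capacity-building",
    "Capacity-building and networking",
    "Policy development",
    "Clinical practice",
    "Health services",
    "Population health",
    "Health outcomes",
    "Health systems strengthening",
    "Engagement and networking",
    "Economic impact")
}

#' Build a scorecard metric
#'
#' A metric is either quantitative (numeric `value` with a mandatory
#' `unit`) or qualitative (text value), with an evidence note and a
#' measurement status. A metric whose status is `"not_available"` carries no
#' value — the gap itself is the information.
#'
#' @param name Metric name, e.g. `"Peer-reviewed publications"`.
#' @param value Numeric or character value; must be absent when
#'   `status = "not_available"`.
#' @param unit Unit for numeric values (e.g. `"papers"`); required when
#'   `value` is numeric.
#' @param evidence Free-text source note.
#' @param status One of `"measured"`, `"estimated"`, `"not_available"`.
#' @return An object of class `fait_metric`.
#' @export
metric <- function(name, value = NULL, unit = NULL, evidence = NULL,
                   status = c("measured", "estimated", "not_available")) {
  status <- match.arg(status)
  if (!is.character(name) || !nzchar(name)) {
    stop("metric `name` must be non-empty text", call. = FALSE)
  }
  if (status == "not_available") {
    if (!is.null(value)) {
      stop(sprintf("metric '%s': status 'not_available' cannot carry a value",
                   name), call. = FALSE)
    }
  } else if (is.numeric(value) && (is.null(unit) || !nzchar(unit))) {
    stop(sprintf("metric '%s': numeric values must carry a unit", name),
         call. = FALSE)
  }
  structure(list(name = name, value = value, unit = unit,
                 evidence = evidence, status = status),
            class = "fait_metric")
}

#' Build a benefit domain
#'
#' @param name Domain name; names outside [fait_domains()] raise a warning
#'   but are accepted.
#' @param metrics List of [metric()] objects.
#' @param outputs Character vector of output/outcome statements.
#' @return An object of class `fait_domain`.
#' @export
domain <- function(name, metrics = list(), outputs = character()) {
  if (!is.character(name) || !nzchar(name)) {
    stop("domain `name` must be non-empty text", call. = FALSE)
  }
  if (!(name %in% fait_domains())) {
    warning(sprintf("domain '%s' is outside the default vocabulary", name),
            call. = FALSE)
  }
  if (inherits(metrics, "fait_metric")) metrics <- list(metrics)
  if (!all(vapply(metrics, inherits, logical(1), "fait_metric"))) {
    stop("`metrics` must be a list of metric() objects", call. = FALSE)
  }
  outputs <- as.character(outputs)
  if (length(metrics) == 0L && length(outputs) == 0L) {
    stop(sprintf("domain '%s' needs at least one metric or output", name),
         call. = FALSE)
  }
  structure(list(name = name, metrics = metrics, outputs = outputs),
            class = "fait_domain")
}

#' Assemble an impact scorecard
#'
#' The scorecard is the integrated presentation artefact: the
#' domains-of-benefit table, a social-return-on-investment block and an
#' optional case-study narrative. When the economic data needed for the
#' SROI block are unavailable, a `data_gap_note` describing how the
#' calculation *could* be done must be supplied instead — an honest gap is
#' part of the assessment.
#'
#' @param project_name Project title.
#' @param domains List of [domain()] objects with unique names.
#' @param sroi_block Optional `sroi_scenarios` (or single `sroi_result`).
#' @param cost_ledger Optional [cost_ledger()] echoed into the rendering.
#' @param data_gap_note Text shown in the SROI block when `sroi_block` is
#'   absent; required in that case.
#' @param narrative Optional [case_narrative()].
#' @return An object of class `fait_scorecard`.
#' @export
scorecard <- function(project_name, domains, sroi_block = NULL,
                      cost_ledger = NULL, data_gap_note = NULL,
                      narrative = NULL) {
  if (inherits(domains, "fait_domain")) domains <- list(domains)
  if (!all(vapply(domains, inherits, logical(1), "fait_domain"))) {
    stop("`domains` must be a list of domain() objects", call. = FALSE)
  }
  nms <- vapply(domains, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate domain name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (inherits(sroi_block, "sroi_result")) {
    sroi_block <- structure(list(sroi_block), class = "sroi_scenarios")
  }
  if (is.null(sroi_block) &&
      (is.null(data_gap_note) || !nzchar(data_gap_note))) {
    stop("a scorecard without an SROI block must carry a `data_gap_note`",
         call. = FALSE)
  }
  structure(list(project_name = project_name, domains = domains,
                 sroi_block = sroi_block, cost_ledger = cost_ledger,
                 data_gap_note = data_gap_note, narrative = narrative),
            class = "fait_scorecard")
}

#' @export
print.fait_scorecard <- function(x, ...) {
  cat(sprintf("Impact scorecard: %s\n", x$project_name))
  cat(sprintf("  %d benefit domains: %s\n", length(x$domains),
              paste(vapply(x$domains, `[[`, character(1), "name"),
                    collapse = "; ")))
  if (!is.null(x$sroi_block)) {
    for (r in x$sroi_block) {
      cat(sprintf("  SROI (%s): %.2f\n", r$scenario_label, r$sroi))
    }
  } else {
    cat("  SROI: not computed (data gap)\n")
  }
  if (!is.null(x$narrative)) cat("  case narrative: present\n")
  invisible(x)
}

# ---- config I/O -----------------------------------------------------------

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

metric_from_list <- function(m) {
  metric(name = m$name, value = m$value, unit = m$unit,
         evidence = m$evidence,
         status = if (is.null(m$status)) "measured" else m$status)
}

domain_from_list <- function(d) {
  domain(name = d$name,
         metrics = lapply(d$metrics, metric_from_list),
         outputs = if (is.null(d$outputs)) character() else
           unlist(d$outputs, use.names = FALSE))
}

#' Load a scorecard from a structured config file
#'
#' Reads a YAML (or JSON) scorecard description and returns a validated
#' [scorecard()]. The config has a `project_name`, a list of `domains`
#' (each with `name`, optional `metrics` — `name`/`value`/`unit`/
#' `evidence`/`status` — and `outputs`), an optional `sroi` section (costs
#' `a` and `b`, `currency`, and either per-scenario benefit totals `c` or a
#' `data_gap_note`), and an optional `narrative` with the five case-study
#' sections.
#'
#' @param path Path to the config file.
#' @return A `fait_scorecard`.
#' @examples
#' cfg <- system.file("extdata", "pacific_salt_scorecard.yaml",
#'                    package = "fait")
#' load_scorecard(cfg)
#' @export
load_scorecard <- function(path) {
  cfg <- tryCatch(read_config_file(path), error = function(e) {
    stop(sprintf("cannot parse scorecard config '%s': %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (is.null(cfg$project_name) || is.null(cfg$domains)) {
    stop("scorecard config needs `project_name` and `domains`", call. = FALSE)
  }
  doms <- lapply(cfg$domains, domain_from_list)
  sroi_block <- NULL
  ledger <- NULL
  gap <- NULL
  if (!is.null(cfg$sroi)) {
    s <- cfg$sroi
    if (!is.null(s$a) && !is.null(s$b)) {
      ledger <- cost_ledger(
        research_cost_a = s$a, implementation_cost_b = s$b,
        horizon = if (is.null(s$horizon)) 5 else s$horizon,
        currency_label = if (is.null(s$currency)) "USD" else s$currency)
    }
    if (!is.null(s$scenarios) && !is.null(ledger)) {
      res <- lapply(s$scenarios, function(sc) {
        sroi(sc$c, ledger, scenario_label = sc$label)
      })
      names(res) <- vapply(s$scenarios, `[[`, character(1), "label")
      sroi_block <- structure(res, class = "sroi_scenarios")
    }
    if (!is.null(s$data_gap_note)) gap <- s$data_gap_note
  } else {
    gap <- "No economic data supplied; SROI not computed."
  }
  narrative <- if (!is.null(cfg$narrative)) {
    do.call(case_narrative, cfg$narrative)
  }
  scorecard(project_name = cfg$project_name, domains = doms,
            sroi_block = sroi_block, cost_ledger = ledger,
            data_gap_note = gap, narrative = narrative)
}

#' Save a scorecard back to YAML
#'
#' Inverse of [load_scorecard()]: a saved scorecard reloads to an identical
#' object (round-trip property).
#'
#' @param sc A `fait_scorecard`.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
save_scorecard <- function(sc, path) {
  stopifnot(inherits(sc, "fait_scorecard"))
  cfg <- list(
    project_name = sc$project_name,
    domains = lapply(sc$domains, function(d) {
      list(name = d$name,
           metrics = lapply(d$metrics, function(m) {
             keep <- !vapply(m, is.null, logical(1))
             unclass(m)[keep]
           }),
           outputs = as.list(d$outputs))
    })
  )
  s <- list()
  if (!is.null(sc$cost_ledger)) {
    s$a <- sc$cost_ledger$research_cost_a
    s$b <- sc$cost_ledger$implementation_cost_b
    s$horizon <- sc$cost_ledger$horizon
    s$currency <- sc$cost_ledger$currency_label
  }
  if (!is.null(sc$sroi_block)) {
    s$scenarios <- lapply(unname(unclass(sc$sroi_block)), function(r) {
      list(label = r$scenario_label, c = r$c)
    })
  }
  if (!is.null(sc$data_gap_note)) s$data_gap_note <- sc$data_gap_note
  if (length(s)) cfg$sroi <- s
  if (!is.null(sc$narrative)) cfg$narrative <- unclass(sc$narrative)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Aggregate numeric scorecard metrics
#'
#' Sums quantitative metrics by unit, never across units (papers are not
#' added to datasets). With `metric_name` given, sums that metric across
#' domains and errors if its occurrences carry different units.
#'
#' @param sc A `fait_scorecard`.
#' @param metric_name Optional metric name to total across domains.
#' @return A data frame with columns `unit` and `total` (and attribute
#'   `"breakdown"`, the per-domain rows); or, with `metric_name`, a single
#'   named total.
#' @examples
#' sc <- load_scorecard(system.file("extdata", "pacific_salt_scorecard.yaml",
#'                                  package = "fait"))
#' aggregate_counts(sc)
#' @export
aggregate_counts <- function(sc, metric_name = NULL) {
  stopifnot(inherits(sc, "fait_scorecard"))
  rows <- do.call(rbind, lapply(sc$domains, function(d) {
    num <- Filter(function(m) is.numeric(m$value), d$metrics)
    if (!length(num)) return(NULL)
    data.frame(domain = d$name,
               metric = vapply(num, `[[`, character(1), "name"),
               unit = vapply(num, `[[`, character(1), "unit"),
               value = vapply(num, function(m) as.numeric(m$value),
                              numeric(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    out <- data.frame(unit = character(), total = numeric())
    attr(out, "breakdown") <- rows
    return(out)
  }
  if (!is.null(metric_name)) {
    sel <- rows[rows$metric == metric_name, , drop = FALSE]
    if (nrow(sel) == 0L) {
      stop(sprintf("no numeric metric named '%s'", metric_name),
           call. = FALSE)
    }
    if (length(unique(sel$unit)) > 1L) {
      stop(sprintf("cannot sum metric '%s' across mismatched units: %s",
                   metric_name, paste(unique(sel$unit), collapse = ", ")),
           call. = FALSE)
    }
    return(setNames(sum(sel$value), unique(sel$unit)))
  }
  totals <- aggregate(value ~ unit, data = rows, FUN = sum)
  names(totals) <- c("unit", "total")
  totals <- totals[order(totals$unit), , drop = FALSE]
  rownames(totals) <- NULL
  attr(totals, "breakdown") <- rows
  totals
}

# ---- rendering ------------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_metric_value <- function(m) {
  if (m$status == "not_available") return("not available")
  if (is.numeric(m$value)) paste(m$value, m$unit) else
    if (is.null(m$value)) "" else as.character(m$value)
}

#' Render a scorecard to Markdown or HTML
#'
#' Produces the presentation document: a Domains of Benefit section with a
#' metric table and output bullets per domain, the Social Return on
#' Investment block (either the cost/benefit/ratio figures per scenario or
#' the data-gap note with the suggested approach), and the case-study
#' narrative when present. Rendering is a pure function of the scorecard:
#' identical inputs give byte-identical output.
#'
#' @param sc A `fait_scorecard`.
#' @param format `"markdown"` or `"html"`.
#' @return A single character string, the rendered document.
#' @export
render_scorecard <- function(sc, format = c("markdown", "html")) {
  stopifnot(inherits(sc, "fait_scorecard"))
  format <- match.arg(format)
  md <- character()
  add <- function(...) md <<- c(md, ...)

  add(sprintf("# Impact scorecard: %s", sc$project_name), "")
  add("## Domains of Benefit", "")
  for (d in sc$domains) {
    add(sprintf("### %s", d$name), "")
    if (length(d$metrics)) {
      add("| Metric | Value | Status | Evidence |",
          "| --- | --- | --- | --- |")
      for (m in d$metrics) {
        add(sprintf("| %s | %s | %s | %s |",
                    m$name, render_metric_value(m), m$status,
                    if (is.null(m$evidence)) "" else m$evidence))
      }
      add("")
    }
    if (length(d$outputs)) {
      add(paste0("- ", d$outputs), "")
    }
  }
  add("## Social Return on Investment", "")
  if (!is.null(sc$cost_ledger)) {
    add(sprintf("- Total project cost (a): %s",
                format_currency(sc$cost_ledger$research_cost_a,
                                sc$cost_ledger$currency_label)),
        sprintf("- Cost of deploying the intervention (b): %s over %g years",
                format_currency(sc$cost_ledger$implementation_cost_b,
                                sc$cost_ledger$currency_label),
                sc$cost_ledger$horizon))
  }
  if (!is.null(sc$sroi_block)) {
    for (r in sc$sroi_block) {
      add(sprintf("- Benefit (c), %s scenario: %s; SROI c / (a + b) = %.2f",
                  r$scenario_label, format_currency(r$c, r$currency_label),
                  r$sroi))
    }
    add("")
  } else {
    add(sprintf("- Not computed due to lack of data. %s", sc$data_gap_note),
        "")
  }
  if (!is.null(sc$narrative)) {
    add("## Case study", "",
        render_narrative(sc$narrative, format = "markdown"))
  }
  doc <- paste(md, collapse = "\n")
  if (format == "html") markdown_to_html(doc) else doc
}

# Minimal deterministic Markdown-to-HTML conversion covering the subset the
# renderers emit: headings, bullet lists, tables and paragraphs.
markdown_to_html <- function(md) {
  lines <- strsplit(md, "\n", fixed = TRUE)[[1]]
  out <- c("<!DOCTYPE html>", "<html><body>")
  in_list <- FALSE
  in_table <- FALSE
  close_blocks <- function() {
    if (in_list) { out <<- c(out, "</ul>"); in_list <<- FALSE }
    if (in_table) { out <<- c(out, "</table>"); in_table <<- FALSE }
  }
  for (ln in lines) {
    if (grepl("^#{1,6} ", ln)) {
      close_blocks()
      lvl <- nchar(sub(" .*$", "", ln))
      txt <- html_escape(sub("^#{1,6} ", "", ln))
      out <- c(out, sprintf("<h%d>%s</h%d>", lvl, txt, lvl))
    } else if (grepl("^- ", ln)) {
      if (in_table) { out <- c(out, "</table>"); in_table <- FALSE }
      if (!in_list) { out <- c(out, "<ul>"); in_list <- TRUE }
      out <- c(out, sprintf("<li>%s</li>", html_escape(sub("^- ", "", ln))))
    } else if (grepl("^\\|", ln)) {
      if (in_list) { out <- c(out, "</ul>"); in_list <- FALSE }
      if (grepl("^\\|[ :-]+\\|", ln) && grepl("---", ln)) next
      if (!in_table) { out <- c(out, "<table>"); in_table <- TRUE }
      cells <- strsplit(gsub("^\\||\\|$", "", ln), "|", fixed = TRUE)[[1]]
      out <- c(out, paste0("<tr>", paste0("<td>",
                                          html_escape(trimws(cells)),
                                          "</td>", collapse = ""), "</tr>"))
    } else if (nzchar(trimws(ln))) {
      close_blocks()
      out <- c(out, sprintf("<p>%s</p>", html_escape(ln)))
    } else {
      close_blocks()
    }
  }
  close_blocks()
  paste(c(out, "</body></html>"), collapse = "\n")
}
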