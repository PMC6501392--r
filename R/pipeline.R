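#' Read a pipeline configuration file
#'
#' One YAML (or JSON) file drives the whole pipeline, with a section per
#' stage: `cohort_params` (or `cohort_file` pointing at a CSV cohort),
#' `epi_params`, `econ_params`, `cost_ledger`, `scale_factor`, `scorecard`
#' (a path, resolved relative to the config file, or an inline scorecard
#' section), optional `logic_model` and `narrative`, `output_dir` and
#' `seed`.
#'
#' @param path Path to the config file.
#' @return A named list of class `fait_config`; the directory of `path` is
#'   kept as attribute `"dir"` for resolving relative paths.
#' @export
fait_config <- function(path) {
  cfg <- tryCatch(read_config_file(path), error = function(e) {
    stop(sprintf("cannot parse pipeline config '%s': %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  structure(cfg, dir = dirname(normalizePath(path)), class = "fait_config")
}

resolve_path <- function(p, dir) {
  if (is.null(dir) || file.exists(p)) p else file.path(dir, p)
}

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

#' Run the full impact-assessment pipeline
#'
#' Wires the stages end to end: simulate (or load) the cohort, summarise it
#' into arm-level statistics, project events/deaths/DALYs averted, monetise
#' them, compute the SROI scenarios, and render the scorecard with the SROI
#' block filled in, alongside the readiness report, the serialised
#' projection and scenario results, and a run manifest (config digest,
#' seed, package version) for provenance. Everything is deterministic given
#' the config and seed.
#'
#' If the readiness audit finds required parameters missing the run stops —
#' unless `allow_partial = TRUE`, in which case the qualitative outputs are
#' still produced and the scorecard carries a data-gap note naming the
#' missing parameters and the suggested approach, instead of an SROI block.
#'
#' @param config A [fait_config()], a path to one, or an equivalent named
#'   list.
#' @param output_dir Where to write the bundle; overrides the config.
#' @param seed Overrides the config seed for cohort generation.
#' @param allow_partial Produce a data-gap bundle instead of failing when
#'   required quantitative parameters are missing.
#' @param format Scorecard output format, `"markdown"` or `"html"`.
#' @return Invisibly, a list of class `fait_bundle` with the `scorecard`
#'   object, `summary`, `impact` (a [fait_impact()] fit or `NULL`),
#'   `readiness`, `logic_validation` (or `NULL`), `manifest` and `files`
#'   (paths written).
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         allow_partial = FALSE,
                         format = c("markdown", "html")) {
  format <- match.arg(format)
  if (is.character(config)) config <- fait_config(config)
  cfg_dir <- attr(config, "dir")
  cfg <- unclass(config)

  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(output_dir)) output_dir <- cfg$output_dir
  if (is.null(output_dir)) {
    stop("no `output_dir` in config or arguments", call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  readiness <- audit_data_readiness(cfg)
  if (!is_ready(readiness) && !allow_partial) {
    stop("pipeline configuration incomplete; missing: ",
         paste(readiness$missing_fields, collapse = ", "),
         " (rerun with allow_partial = TRUE for a data-gap bundle)",
         call. = FALSE)
  }

  # --- quantitative arm -----------------------------------------------
  summary <- NULL
  impact <- NULL
  if (is_ready(readiness)) {
    if (!is.null(cfg$cohort_file)) {
      cohort <- read_cohort(resolve_path(cfg$cohort_file, cfg_dir))
    } else {
      cp_args <- if (is.null(cfg$cohort_params)) list() else cfg$cohort_params
      if (!is.null(cfg$seed)) cp_args$seed <- cfg$seed
      if (is.null(cp_args$seed)) {
        stop("cohort generation needs a `seed` (config or argument)",
             call. = FALSE)
      }
      cohort <- generate_cohort(do.call(cohort_params, cp_args))
    }
    summary <- summarize_cohort(cohort)
    epi <- do.call(epi_params, cfg$epi_params)
    econ <- do.call(econ_params, cfg$econ_params)
    ledger <- do.call(cost_ledger, cfg$cost_ledger)
    impact <- fait_impact(
      summary, epi = epi, econ = econ, ledger = ledger,
      n_exposed = cfg$n_exposed,
      scale_factor = if (is.null(cfg$scale_factor)) 1 else cfg$scale_factor)
  }

  # --- scorecard -------------------------------------------------------
  sc <- NULL
  if (!is.null(cfg$scorecard)) {
    sc <- if (is.character(cfg$scorecard)) {
      load_scorecard(resolve_path(cfg$scorecard, cfg_dir))
    } else {
      tmp <- tempfile(fileext = ".yaml")
      on.exit(unlink(tmp), add = TRUE)
      yaml::write_yaml(cfg$scorecard, tmp)
      load_scorecard(tmp)
    }
    if (!is.null(impact)) {
      sc <- scorecard(project_name = sc$project_name, domains = sc$domains,
                      sroi_block = impact$scenarios,
                      cost_ledger = impact$ledger,
                      narrative = sc$narrative)
    } else {
      gap <- paste0(
        "Missing parameters: ",
        paste(readiness$missing_fields, collapse = ", "), ". ",
        paste(readiness$suggested_approach, collapse = " "))
      sc <- scorecard(project_name = sc$project_name, domains = sc$domains,
                      sroi_block = NULL, cost_ledger = NULL,
                      data_gap_note = gap, narrative = sc$narrative)
    }
  }

  # --- qualitative -----------------------------------------------------
  logic_validation <- NULL
  if (!is.null(cfg$logic_model)) {
    lm_cfg <- if (is.character(cfg$logic_model)) {
      read_config_file(resolve_path(cfg$logic_model, cfg_dir))
    } else {
      cfg$logic_model
    }
    logic_validation <- validate_logic_model(do.call(logic_model, lm_cfg))
  }

  # --- write the bundle ------------------------------------------------
  files <- character()
  put <- function(name, writer) {
    p <- file.path(output_dir, name)
    writer(p)
    files[[name]] <<- p
  }
  if (!is.null(sc)) {
    ext <- if (format == "html") "html" else "md"
    put(paste0("scorecard.", ext), function(p) {
      writeLines(render_scorecard(sc, format = format), p)
    })
  }
  if (!is.null(summary)) {
    put("trial_summary.json",
        function(p) write_json_out(unclass(summary), p))
  }
  if (!is.null(impact)) {
    put("projection.json",
        function(p) write_json_out(unclass(impact$projection), p))
    put("sroi.json", function(p) {
      write_json_out(lapply(unclass(impact$scenarios), unclass), p)
    })
  }
  if (!is.null(sc) && !is.null(sc$narrative)) {
    put("narrative.md", function(p) {
      writeLines(render_narrative(sc$narrative, format = "markdown"), p)
    })
  }
  if (!is.null(logic_validation)) {
    put("logic_validation.json",
        function(p) write_json_out(unclass(logic_validation), p))
  }
  put("readiness.json", function(p) write_json_out(unclass(readiness), p))
  manifest <- list(package = "fait",
                   version = as.character(utils::packageVersion("fait")),
                   config_digest = config_digest(cfg),
                   seed = cfg$seed,
                   partial = !is_ready(readiness),
                   outputs = names(files))
  put("manifest.json", function(p) write_json_out(manifest, p))

  invisible(structure(list(scorecard = sc, summary = summary,
                           impact = impact, readiness = readiness,
                           logic_validation = logic_validation,
                           manifest = manifest, files = files),
                      class = "fait_bundle"))
}

#' @export
print.fait_bundle <- function(x, ...) {
  cat("FAIT report bundle\n")
  cat(sprintf("  partial: %s; files: %s\n",
              x$manifest$partial, paste(x$manifest$outputs, collapse = ", ")))
  if (!is.null(x$impact)) print(x$impact$scenarios)
  if (!is.null(x$readiness) && !is_ready(x$readiness)) print(x$readiness)
  invisible(x)
}
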