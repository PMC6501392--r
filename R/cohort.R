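#' Parameters for the synthetic screening cohort
#'
#' Describes a two-arm community cardiovascular screening programme: a target
#' cohort of which a fraction is screened, a fraction of the screened found at
#' high risk of a CVD event, and arm-specific probabilities that a high-risk
#' individual receives appropriate medication. Systolic blood pressure (SBP)
#' is drawn from a normal distribution; medication lowers it so that the
#' expected difference in mean SBP between the arms, among high-risk
#' individuals, equals `treatment_effect_sbp` (see Details).
#'
#' The defaults are calibrated to a community screening trial in which 91% of
#' a target cohort of about 12,100 was screened, 22% of those screened were
#' high-risk, 80% of high-risk individuals in the intervention arm received
#' appropriate medication against 16% under usual care, and the arms differed
#' by 13 mmHg in mean systolic blood pressure among high-risk individuals.
#'
#' @details
#' `treatment_effect_sbp` parameterises the *between-arm contrast*, the
#' quantity such trials report, not the per-person pharmacological effect.
#' Internally each treated high-risk individual (in either arm) has mean SBP
#' lowered by `treatment_effect_sbp / (p_treated_intervention -
#' p_treated_control)`, so that the expected difference of arm means among
#' high-risk individuals is exactly `treatment_effect_sbp`. A positive effect
#' therefore requires `p_treated_intervention > p_treated_control`.
#'
#' @param n_target Integer, size of the target cohort (persons). The default
#'   12088 back-solves 91% screening coverage to about 11,000 screened.
#' @param p_screen Probability a target-cohort member is screened.
#' @param p_highrisk Probability a screened person is classified high-risk.
#' @param p_treated_intervention,p_treated_control Probability a high-risk
#'   person receives appropriate medication, by arm.
#' @param sbp_mean_control Mean untreated systolic blood pressure, mmHg.
#' @param sbp_sd Within-arm SBP standard deviation, mmHg.
#' @param treatment_effect_sbp Expected between-arm difference in mean SBP
#'   among high-risk individuals, mmHg (control minus intervention; >= 0).
#' @param allocation_fraction Probability of allocation to the intervention
#'   arm (individual Bernoulli allocation).
#' @param age_mean,age_sd,age_min Age model: normal with this mean and sd,
#'   truncated below at `age_min` years.
#' @param seed Integer RNG seed; mandatory so every cohort is reproducible.
#'
#' @return An object of class `cohort_params` (a validated named list).
#' @seealso [generate_cohort()], [summarize_cohort()]
#' @examples
#' p <- cohort_params(seed = 1)
#' coh <- generate_cohort(p)
#' summarize_cohort(coh)
#' @export
cohort_params <- function(n_target = 12088L,
                          p_screen = 0.91,
                          p_highrisk = 0.22,
                          p_treated_intervention = 0.80,
                          p_treated_control = 0.16,
                          sbp_mean_control = 140,
                          sbp_sd = 15,
                          treatment_effect_sbp = 13,
                          allocation_fraction = 0.5,
                          age_mean = 59,
                          age_sd = 8,
                          age_min = 18,
                          seed) {
  if (missing(seed)) {
    stop("`seed` is mandatory: cohorts must be reproducible", call. = FALSE)
  }
  p <- list(
    n_target = as.integer(n_target), p_screen = p_screen,
    p_highrisk = p_highrisk,
    p_treated_intervention = p_treated_intervention,
    p_treated_control = p_treated_control,
    sbp_mean_control = sbp_mean_control, sbp_sd = sbp_sd,
    treatment_effect_sbp = treatment_effect_sbp,
    allocation_fraction = allocation_fraction,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    seed = as.integer(seed)
  )
  probs <- c("p_screen", "p_highrisk", "p_treated_intervention",
             "p_treated_control", "allocation_fraction")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  if (is.na(p$n_target) || p$n_target < 1L) {
    stop("`n_target` must be a positive integer (empty cohorts are not generated)",
         call. = FALSE)
  }
  if (!is.numeric(p$sbp_sd) || p$sbp_sd <= 0) {
    stop("`sbp_sd` must be > 0", call. = FALSE)
  }
  if (!is.numeric(p$treatment_effect_sbp) || p$treatment_effect_sbp < 0) {
    stop("`treatment_effect_sbp` must be >= 0", call. = FALSE)
  }
  if (p$treatment_effect_sbp > 0 &&
      p$p_treated_intervention <= p$p_treated_control) {
    stop(paste0("a positive `treatment_effect_sbp` requires ",
                "`p_treated_intervention` > `p_treated_control` ",
                "(the effect parameterises the between-arm contrast)"),
         call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  target cohort:    %d persons (seed %d)\n", x$n_target, x$seed))
  cat(sprintf("  screening:        %.0f%%; high-risk | screened: %.0f%%\n",
              100 * x$p_screen, 100 * x$p_highrisk))
  cat(sprintf("  treated | high-risk: %.0f%% (intervention) vs %.0f%% (control)\n",
              100 * x$p_treated_intervention, 100 * x$p_treated_control))
  cat(sprintf("  SBP: N(%.0f, %.0f^2) mmHg; between-arm effect %.1f mmHg\n",
              x$sbp_mean_control, x$sbp_sd, x$treatment_effect_sbp))
  invisible(x)
}

# Run code under a local RNG state: seeds deterministically, restores the
# caller's .Random.seed so no global state leaks.
with_cohort_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Normal deviates truncated below at `lower` by resampling.
rnorm_lower <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate a synthetic two-arm screening cohort
#'
#' Draws one record per member of the target cohort: arm allocation,
#' screening, high-risk and treatment statuses as independent Bernoulli
#' variables with the probabilities in `params`, systolic blood pressure from
#' a normal distribution (lowered for treated high-risk individuals so the
#' expected arm contrast equals `treatment_effect_sbp`; see
#' [cohort_params()]), and age from a truncated normal with mean 59 years.
#'
#' The draw is fully determined by `params$seed` and leaves the caller's RNG
#' state untouched.
#'
#' @param params A [cohort_params()] object.
#' @return A `data.frame` of class `fait_cohort` with columns `id`, `arm`
#'   (`"intervention"`/`"control"`), `screened`, `high_risk`, `treated`
#'   (logicals; `high_risk` implies `screened`, `treated` implies
#'   `high_risk`), `sbp` (mmHg, positive) and `age` (years). The generating
#'   parameters are attached as attribute `"params"`.
#' @examples
#' coh <- generate_cohort(cohort_params(n_target = 500, seed = 42))
#' table(coh$arm, coh$high_risk)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("`params` must be a `cohort_params` object", call. = FALSE)
  }
  n <- params$n_target
  with_cohort_seed(params$seed, {
    arm <- ifelse(rbinom(n, 1L, params$allocation_fraction) == 1L,
                  "intervention", "control")
    screened <- rbinom(n, 1L, params$p_screen) == 1L
    high_risk <- screened & (rbinom(n, 1L, params$p_highrisk) == 1L)
    p_treat <- ifelse(arm == "intervention",
                      params$p_treated_intervention,
                      params$p_treated_control)
    treated <- high_risk & (rbinom(n, 1L, p_treat) == 1L)

    # Per-treated-person SBP reduction chosen so the expected between-arm
    # contrast among high-risk individuals equals treatment_effect_sbp.
    gap <- params$p_treated_intervention - params$p_treated_control
    per_treated_effect <- if (params$treatment_effect_sbp == 0) 0 else {
      params$treatment_effect_sbp / gap
    }
    sbp <- rnorm_lower(n, params$sbp_mean_control, params$sbp_sd, lower = 1)
    sbp[treated] <- pmax(sbp[treated] - per_treated_effect, 1)

    age <- rnorm_lower(n, params$age_mean, params$age_sd, params$age_min)

    structure(
      data.frame(id = seq_len(n), arm = arm, screened = screened,
                 high_risk = high_risk, treated = treated,
                 sbp = sbp, age = age),
      params = params,
      class = c("fait_cohort", "data.frame")
    )
  })
}

#' Simulate cohorts from a parameter set
#'
#' `simulate()` method for [cohort_params()]: returns a list of `nsim`
#' cohorts generated with consecutive seeds starting at `seed` (default:
#' the seed stored in the parameter object).
#'
#' @param object A `cohort_params` object.
#' @param nsim Number of cohorts.
#' @param seed First seed; cohort `i` uses `seed + i - 1`.
#' @param ... Unused.
#' @return A list of `fait_cohort` data frames.
#' @export
simulate.cohort_params <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- if (is.null(seed)) object$seed else as.integer(seed)
  lapply(seq_len(nsim) - 1L, function(i) {
    p <- object
    p$seed <- seed + i
    generate_cohort(p)
  })
}

#' Summarise a cohort into arm-level trial statistics
#'
#' Computes the empirical summary the projection model consumes: screening
#' coverage, the high-risk fraction among the screened, per-arm high-risk
#' counts and treatment coverage, and the difference in mean systolic blood
#' pressure between the arms among high-risk individuals (control minus
#' intervention; reported as estimated, which may be negative).
#'
#' @param cohort A `fait_cohort` data frame (or any data frame with the same
#'   columns).
#' @return An object of class `trial_summary`: a list with `n_target`,
#'   `n_screened`, `screening_coverage`, `highrisk_fraction`, `n_highrisk`
#'   (named vector by arm), `treated_fraction_by_arm` (named vector) and
#'   `delta_sbp_highrisk` (mmHg).
#' @examples
#' summarize_cohort(generate_cohort(cohort_params(n_target = 2000, seed = 7)))
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("`cohort` must be a non-empty cohort data frame", call. = FALSE)
  }
  need <- c("arm", "screened", "high_risk", "treated", "sbp")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  arms <- c("intervention", "control")
  hr <- cohort[cohort$high_risk, , drop = FALSE]
  n_hr <- vapply(arms, function(a) sum(hr$arm == a), integer(1))
  if (any(n_hr == 0L)) {
    stop("undefined contrast: arm(s) ",
         paste(arms[n_hr == 0L], collapse = ", "),
         " contain no high-risk individuals", call. = FALSE)
  }
  mean_sbp <- vapply(arms, function(a) mean(hr$sbp[hr$arm == a]), numeric(1))
  treated_frac <- vapply(arms, function(a) mean(hr$treated[hr$arm == a]),
                         numeric(1))
  structure(list(
    n_target = nrow(cohort),
    n_screened = sum(cohort$screened),
    screening_coverage = mean(cohort$screened),
    highrisk_fraction = sum(cohort$high_risk) / sum(cohort$screened),
    n_highrisk = n_hr,
    treated_fraction_by_arm = treated_frac,
    delta_sbp_highrisk = unname(mean_sbp["control"] - mean_sbp["intervention"])
  ), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("Trial summary\n")
  cat(sprintf("  screened: %d of %d (%.1f%% coverage)\n",
              x$n_screened, x$n_target, 100 * x$screening_coverage))
  cat(sprintf("  high-risk among screened: %.1f%% (n = %d intervention, %d control)\n",
              100 * x$highrisk_fraction,
              x$n_highrisk[["intervention"]], x$n_highrisk[["control"]]))
  cat(sprintf("  treated among high-risk: %.1f%% vs %.1f%% (intervention vs control)\n",
              100 * x$treated_fraction_by_arm[["intervention"]],
              100 * x$treated_fraction_by_arm[["control"]]))
  cat(sprintf("  between-arm mean SBP difference (high-risk): %.2f mmHg\n",
              x$delta_sbp_highrisk))
  invisible(x)
}

#' Read and write cohort tables as CSV
#'
#' Cohorts are exchanged as plain CSV with a header row and one record per
#' person; logical status columns are restored on read.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns a `fait_cohort` data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("screened", "high_risk", "treated")) {
    if (nm %in% names(x)) x[[nm]] <- as.logical(x[[nm]])
  }
  class(x) <- c("fait_cohort", "data.frame")
  x
}
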