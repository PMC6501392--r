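full_model <- function() {
  logic_model(
    need = "High untreated CVD burden",
    activities = c("Train lay health workers", "Deploy decision support"),
    outputs = c("Screening records", "Referral pathway"),
    end_users = c("District health authority"),
    anticipated_impact = c("Lower blood pressure in high-risk adults"),
    links = list(c("Train lay health workers", "Screening records")))
}

test_that("a fully populated logic model validates cleanly", {
  v <- validate_logic_model(full_model())
  expect_true(v$valid)
  expect_length(v$empty_sections, 0)
  expect_length(v$dangling_links, 0)
})

test_that("validation names empty sections and dangling links without throwing", {
  m <- full_model()
  m$end_users <- character()
  v <- validate_logic_model(m)
  expect_false(v$valid)
  expect_equal(v$empty_sections, "end_users")

  m2 <- full_model()
  m2$links <- c(m2$links, list(c("Nonexistent activity", "Screening records")))
  v2 <- validate_logic_model(m2)
  expect_false(v2$valid)
  expect_length(v2$dangling_links, 1)
  expect_equal(v2$dangling_links[[1]][1], "Nonexistent activity")
})

test_that("a model passing validation renders its narrative chain without error", {
  # exhaustiveness: valid model => every link endpoint resolvable
  v <- validate_logic_model(full_model())
  expect_true(v$valid)
  expect_no_error(print(v))
})

test_that("case narratives require all five sections", {
  nar <- case_narrative("a", "b", "c", "d", "e")
  expect_s3_class(nar, "case_narrative")
  expect_error(case_narrative("a", "b", "c", "d", ""), "lessons")
  expect_error(case_narrative("", "b", "c", "d", "e"), "need")
})

test_that("narrative rendering is deterministic with canonical heading order", {
  nar <- case_narrative("N", "R", "O", "I", "L")
  md <- render_narrative(nar)
  expect_identical(md, render_narrative(nar))
  heads <- regmatches(md, gregexpr("### [A-Za-z ]+", md))[[1]]
  expect_equal(heads, c("### Need", "### Research response", "### Outcome",
                        "### Impact", "### Lessons"))
  # hand-emptied section fails loudly, naming the section
  nar$lessons <- " "
  expect_error(render_narrative(nar), "lessons")
  expect_match(render_narrative(case_narrative("N", "R", "O", "I", "L"),
                                format = "html"), "<h3>Need</h3>")
})

complete_cfg <- function() {
  list(epi_params = list(baseline_event_risk = 0.194, case_fatality = 0.3),
       econ_params = list(gni_per_capita = 3540,
                          hosp_cost_per_event = 4560),
       cost_ledger = list(research_cost_a = 1e6,
                          implementation_cost_b = 328.3e6))
}

test_that("a complete configuration audits as ready", {
  rep <- audit_data_readiness(complete_cfg())
  expect_true(is_ready(rep))
  expect_length(rep$missing_fields, 0)
  expect_length(rep$affected_outputs, 0)
})

test_that("missing parameters block exactly their downstream outputs", {
  cfg <- complete_cfg()
  cfg$epi_params$baseline_event_risk <- NULL
  cfg$econ_params <- NULL
  rep <- audit_data_readiness(cfg)
  expect_setequal(rep$missing_fields,
                  c("baseline_event_risk", "hosp_cost_per_event",
                    "gni_per_capita"))
  expect_true(all(c("total benefit (c)", "SROI") %in% rep$affected_outputs))
  expect_true("events averted" %in% rep$affected_outputs)

  # only the hospitalisation cost missing: DALY outputs unaffected
  cfg2 <- complete_cfg()
  cfg2$econ_params$hosp_cost_per_event <- NULL
  rep2 <- audit_data_readiness(cfg2)
  expect_equal(rep2$missing_fields, "hosp_cost_per_event")
  expect_setequal(rep2$affected_outputs,
                  c("health_system_savings", "total benefit (c)", "SROI"))
  expect_false("DALYs averted" %in% rep2$affected_outputs)
})

test_that("implementation cost can be satisfied by an annual cost and horizon", {
  cfg <- complete_cfg()
  cfg$cost_ledger$implementation_cost_b <- NULL
  expect_false(is_ready(audit_data_readiness(cfg)))
  cfg$cost_ledger$annual_implementation_cost <- 5e5
  cfg$cost_ledger$horizon <- 5
  expect_true(is_ready(audit_data_readiness(cfg)))
})

test_that("the audit is monotone: adding values never grows the gaps", {
  full <- complete_cfg()
  fields <- list(c("epi_params", "baseline_event_risk"),
                 c("epi_params", "case_fatality"),
                 c("econ_params", "hosp_cost_per_event"),
                 c("econ_params", "gni_per_capita"),
                 c("cost_ledger", "research_cost_a"),
                 c("cost_ledger", "implementation_cost_b"))
  set.seed(31)
  for (i in 1:10) {
    drop <- sample(length(fields), sample(0:5, 1))
    cfg <- full
    for (j in drop) cfg[[fields[[j]][1]]][[fields[[j]][2]]] <- NULL
    before <- audit_data_readiness(cfg)
    # restore one dropped field (if any): missing set must not grow
    if (length(drop)) {
      k <- fields[[drop[1]]]
      cfg[[k[1]]][[k[2]]] <- full[[k[1]]][[k[2]]]
      after <- audit_data_readiness(cfg)
      expect_true(all(after$missing_fields %in% before$missing_fields))
      expect_lt(length(after$missing_fields), length(before$missing_fields))
      expect_true(all(after$affected_outputs %in% before$affected_outputs))
    }
  }
})
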