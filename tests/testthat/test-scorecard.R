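test_that("metric and domain constructors enforce their invariants", {
  expect_error(metric("", 1, unit = "papers"), "non-empty")
  expect_error(metric("Papers", 7), "unit")
  expect_error(metric("Papers", 7, unit = "papers", status = "not_available"),
               "cannot carry a value")
  expect_silent(metric("Salt intake", status = "not_available"))
  expect_error(domain("Advance knowledge"), "at least one")
  expect_warning(domain("Underwater basket weaving", outputs = "x"),
                 "outside the default vocabulary")
})

test_that("scorecards demand unique domains and honest data gaps", {
  d1 <- domain("Advance knowledge", outputs = "x")
  d2 <- domain("Economic impact", outputs = "y")
  expect_error(scorecard("P", list(d1, d1), data_gap_note = "n"),
               "duplicate domain")
  expect_error(scorecard("P", list(d1, d2)), "data_gap_note")
  expect_silent(scorecard("P", list(d1, d2), data_gap_note = "no data yet"))
})

test_that("the published fixtures load with their full structure", {
  pac <- suppressWarnings(
    load_scorecard(system.file("extdata", "pacific_salt_scorecard.yaml",
                               package = "fait")))
  expect_s3_class(pac, "fait_scorecard")
  expect_length(pac$domains, 5)
  expect_null(pac$sroi_block)
  expect_match(pac$data_gap_note, "could not be converted|not collected",
               ignore.case = TRUE)
  expect_s3_class(pac$narrative, "case_narrative")

  sh <- load_scorecard(system.file("extdata", "smarthealth_scorecard.yaml",
                                   package = "fait"))
  expect_length(sh$domains, 5)
  expect_named(sh$sroi_block, c("conservative", "base"))
  expect_equal(round(sh$sroi_block$conservative$sroi, 2), 2.18)
  expect_equal(round(sh$sroi_block$base$sroi, 2), 2.76)
})

test_that("a config with duplicate domains fails validation", {
  cfg <- list(project_name = "Dup",
              domains = list(
                list(name = "Economic impact", outputs = list("a")),
                list(name = "Economic impact", outputs = list("b"))))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  expect_error(load_scorecard(path), "duplicate domain")
})

test_that("numeric metrics aggregate by unit, never across units", {
  sc <- make_mini_scorecard()
  agg <- aggregate_counts(sc)
  expect_equal(agg$total[agg$unit == "papers"], 3)
  expect_equal(agg$total[agg$unit == "datasets"], 1)
  expect_equal(agg$total[agg$unit == "grants"], 2)
  expect_equal(nrow(agg), 3)   # no cross-unit sums

  pac <- suppressWarnings(
    load_scorecard(system.file("extdata", "pacific_salt_scorecard.yaml",
                               package = "fait")))
  # direct + linked publications total 14, with the 7 + 7 breakdown intact
  expect_equal(unname(aggregate_counts(pac)$total[
    aggregate_counts(pac)$unit == "papers"]), 14)
  br <- attr(aggregate_counts(pac), "breakdown")
  expect_setequal(br$value[br$unit == "papers"], c(7, 7))
})

test_that("metric-level totals refuse mismatched units", {
  sc <- scorecard(
    "P",
    list(domain("Advance knowledge",
                metrics = list(metric("Output count", 3, unit = "papers"))),
         domain("Economic impact",
                metrics = list(metric("Output count", 2, unit = "grants")))),
    data_gap_note = "none yet")
  expect_error(aggregate_counts(sc, metric_name = "Output count"),
               "mismatched units")
  expect_equal(unname(aggregate_counts(make_mini_scorecard(),
                                       metric_name = "Publications")), 3)
})

test_that("an all-text scorecard aggregates to an empty summary", {
  sc <- scorecard("P", list(domain("Advance knowledge", outputs = "x")),
                  data_gap_note = "n")
  agg <- aggregate_counts(sc)
  expect_equal(nrow(agg), 0)
})

test_that("load -> save -> load round-trips the scorecard", {
  for (fixture in c("pacific_salt_scorecard.yaml",
                    "smarthealth_scorecard.yaml")) {
    sc <- suppressWarnings(
      load_scorecard(system.file("extdata", fixture, package = "fait")))
    path <- withr::local_tempfile(fileext = ".yaml")
    save_scorecard(sc, path)
    sc2 <- suppressWarnings(load_scorecard(path))
    expect_equal(sc2, sc, ignore_attr = FALSE)
  }
})

test_that("rendering is deterministic and reflects the SROI state", {
  sh <- load_scorecard(system.file("extdata", "smarthealth_scorecard.yaml",
                                   package = "fait"))
  md1 <- render_scorecard(sh)
  expect_identical(md1, render_scorecard(sh))
  expect_match(md1, "conservative scenario.*SROI c / \\(a \\+ b\\) = 2.18")
  expect_match(md1, "base scenario.*2.76")
  expect_match(md1, "## Case study")

  pac <- suppressWarnings(
    load_scorecard(system.file("extdata", "pacific_salt_scorecard.yaml",
                               package = "fait")))
  md2 <- render_scorecard(pac)
  expect_match(md2, "Not computed due to lack of data")

  html <- render_scorecard(sh, format = "html")
  expect_match(html, "^<!DOCTYPE html>")
  expect_match(html, "<h2>Social Return on Investment</h2>", fixed = TRUE)
  expect_error(render_scorecard(sh, format = "pdf"))
})

test_that("not-available metrics render with an explanatory note", {
  sc <- scorecard(
    "P", list(domain("Population health",
                     metrics = list(metric("Salt intake",
                                           status = "not_available")))),
    data_gap_note = "no data")
  expect_match(render_scorecard(sc), "Salt intake \\| not available")
})
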