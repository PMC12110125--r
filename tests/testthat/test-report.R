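test_that("the full analysis reports the clinic's free capacity and tables", {
  report <- analyze_workload(dental_clinic_fixture())
  expect_identical(report$totals$difference, 1418)
  # report totals equal recomputed sums of the report's own table
  expect_equal(report$totals$normative, sum(report$workload$normative))
  expect_equal(report$totals$actual, sum(report$workload$actual))
  reserve <- report$entropy[report$entropy$quantity == "reserve", ]
  expect_identical(reserve$group,
                   c("All Employees", "Doctors", "Orthodontist", "Therapist",
                     "Hygienist", "Nurse"))
  expect_identical(reserve$member_count, c(13L, 2L, 1L, 1L, 2L, 9L))
  expect_equal(reserve$total_credits, c(3301, 130, 10, 120, 625, 2546))
  expect_equal(reserve$entropy,
               c(3.299140, 0.391244, 0, 0, 0.998846, 2.809968),
               tolerance = 1e-5)
  # rendered values come from the entropy module itself: no drift
  wt <- report$workload
  expect_identical(reserve, entropy_table(wt, "reserve"))
})

test_that("an empty log analyzes to full underload with reserve equal to capacity", {
  data <- dental_clinic_fixture()
  data$log <- data$log[0, ]
  report <- analyze_workload(data)
  expect_true(all(report$workload$relative == 0))
  expect_identical(report$totals$reserve_total, report$totals$normative)
})

test_that("text rendering is deterministic and shows untriggered cases with evidence", {
  report <- analyze_workload(dental_clinic_fixture())
  a <- render_report(report, "text")
  b <- render_report(analyze_workload(dental_clinic_fixture()), "text")
  expect_identical(a, b)
  expect_match(a, "Case 1: not triggered")
  expect_match(a, "Case 4: not triggered")
  expect_match(a, "H_R=")
  expect_match(a, "difference 1418")
})

test_that("JSON rendering re-parses to the same values at the configured precision", {
  report <- analyze_workload(dental_clinic_fixture())
  parsed <- jsonlite::fromJSON(render_report(report, "json"))
  expect_equal(parsed$totals$difference, 1418)
  expect_equal(parsed$workload$normative, report$workload$normative,
               tolerance = 1e-6)
  expect_equal(parsed$entropy$entropy, report$entropy$entropy,
               tolerance = 1e-6)
  expect_identical(parsed$scenarios$triggered, rep(FALSE, 4))
})

test_that("CSV rendering carries the evenness tables row-for-row", {
  report <- analyze_workload(dental_clinic_fixture())
  rendered <- render_report(report, "csv")
  expect_setequal(names(rendered), c("workload", "entropy", "scenarios"))
  entropy <- readr::read_csv(I(rendered[["entropy"]]), show_col_types = FALSE)
  row <- entropy[entropy$group == "All Employees" &
                   entropy$quantity == "reserve", ]
  expect_identical(row$member_count, 13)
  expect_equal(row$total_credits, 3301)
  expect_error(render_report(report, "yaml"))
})

test_that("the command-line interface drives the same pipeline end to end", {
  dir <- withr::local_tempdir()
  fixture_dir <- file.path(dir, "clinic")
  expect_identical(suppressMessages(
    evenwork_main(c("fixture", "--out", fixture_dir))), 0L)
  expect_setequal(list.files(fixture_dir),
                  c("roster.csv", "params.csv", "catalog.csv", "log.csv"))

  args <- c("--roster", file.path(fixture_dir, "roster.csv"),
            "--params", file.path(fixture_dir, "params.csv"),
            "--catalog", file.path(fixture_dir, "catalog.csv"),
            "--log", file.path(fixture_dir, "log.csv"),
            "--period-days", "5")
  expect_identical(suppressMessages(evenwork_main(c("validate", args))), 0L)

  out_json <- file.path(dir, "report.json")
  expect_identical(suppressMessages(evenwork_main(
    c("analyze", args, "--format", "json", "--out", out_json))), 0L)
  parsed <- jsonlite::fromJSON(out_json)
  expect_equal(parsed$totals$normative, 21270)

  sim_dir <- file.path(dir, "sim")
  expect_identical(suppressMessages(evenwork_main(
    c("simulate", "--seed", "3", "--out", sim_dir))), 0L)
  sim <- read_clinic_data(file.path(sim_dir, "roster.csv"),
                          file.path(sim_dir, "params.csv"),
                          file.path(sim_dir, "catalog.csv"),
                          file.path(sim_dir, "log.csv"), period_days = 5)
  expect_true(is_valid(validate_clinic_data(sim)))

  expect_identical(suppressMessages(evenwork_main("frobnicate")), 2L)
  expect_identical(suppressMessages(evenwork_main(character(0))), 2L)

  # a broken dataset exits 1 from validate
  bad <- dental_clinic_fixture()
  bad$roster$share[1] <- 2
  bad_dir <- file.path(dir, "bad")
  write_clinic_data(bad, bad_dir)
  bad_args <- c("--roster", file.path(bad_dir, "roster.csv"),
                "--params", file.path(bad_dir, "params.csv"),
                "--catalog", file.path(bad_dir, "catalog.csv"),
                "--log", file.path(bad_dir, "log.csv"),
                "--period-days", "5")
  expect_identical(suppressMessages(evenwork_main(c("validate", bad_args))), 1L)
})

test_that("YAML configuration overrides thresholds and supergroups", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "thresholds:",
    "  imbalance_ratio: 1.05",
    "supergroups:",
    "  Doctors:",
    "    - Orthodontist",
    "    - Surgeon",
    "    - Therapist",
    "  Support:",
    "    - Hygienist",
    "    - Nurse",
    "decimal_places: 4"
  ), cfg_path)
  config <- read_analysis_config(cfg_path)
  expect_equal(config$thresholds$imbalance_ratio, 1.05)
  expect_equal(config$thresholds$near_zero_fraction, 0.25)
  expect_identical(config$decimal_places, 4L)
  report <- analyze_workload(dental_clinic_fixture(), config)
  support <- report$entropy[report$entropy$group == "Support" &
                              report$entropy$quantity == "reserve", ]
  expect_identical(support$member_count, 11L)  # 2 hygienists + 9 nurses
})
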