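#' Analysis configuration
#'
#' Bundles the knobs of a full workload analysis: the scenario thresholds,
#' the supergroup taxonomy used for group-level entropy tables, the output
#' format and the decimal precision of rendered reports.
#'
#' @param thresholds A [scenario_thresholds()] object.
#' @param supergroups Named list mapping supergroup names to category
#'   vectors; see [default_supergroups()].
#' @param output_format One of `"text"`, `"json"`, `"csv"` (default used by
#'   the command-line interface).
#' @param decimal_places Decimals in rendered tables (default 6, matching
#'   the precision entropy values are conventionally reported at).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(thresholds = scenario_thresholds(),
                            supergroups = default_supergroups(),
                            output_format = c("text", "json", "csv"),
                            decimal_places = 6L) {
  output_format <- match.arg(output_format)
  stopifnot(inherits(thresholds, "scenario_thresholds"),
            is.list(supergroups), decimal_places >= 0)
  structure(list(thresholds = thresholds, supergroups = supergroups,
                 output_format = output_format,
                 decimal_places = as.integer(decimal_places)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors [analysis_config()]: top-level keys `thresholds` (with
#' `near_max_fraction`, `near_zero_fraction`, `imbalance_ratio`),
#' `supergroups` (name -> list of categories), `output_format`,
#' `decimal_places`. Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  th <- raw$thresholds %||% list()
  defaults <- scenario_thresholds()
  analysis_config(
    thresholds = scenario_thresholds(
      near_max_fraction = th$near_max_fraction %||% defaults$near_max_fraction,
      near_zero_fraction = th$near_zero_fraction %||% defaults$near_zero_fraction,
      imbalance_ratio = th$imbalance_ratio %||% defaults$imbalance_ratio),
    supergroups = lapply(raw$supergroups %||% default_supergroups(),
                         as.character),
    output_format = raw$output_format %||% "text",
    decimal_places = raw$decimal_places %||% 6L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full workload-evenness analysis
#'
#' Executes the complete pipeline on a validated dataset: per-employee
#' normative and actual workloads; institution totals and their difference;
#' the workload-distribution entropy for all staff with a per-category and
#' per-supergroup drill-down; the free-time-reserve and excess-credit
#' entropy tables; and the four managerial decision scenarios at
#' institution scope.
#'
#' @param data A [clinic_data()] object.
#' @param config An [analysis_config()].
#' @return A `workload_report`: list with elements `workload` (the
#'   [workload_table()]), `totals` ([workload_totals()]), `entropy` (all
#'   [entropy_table()] rows for relative workload, reserve and excess),
#'   `scenarios` ([evaluate_scenarios()] findings), `config`, and
#'   `provenance` (input digests where the data came from files, generator
#'   seed where it was simulated).
#' @export
#' @examples
#' report <- analyze_workload(dental_clinic_fixture())
#' report$totals$difference  # 1418 free credits
analyze_workload <- function(data, config = analysis_config()) {
  stopifnot(inherits(data, "clinic_data"), inherits(config, "analysis_config"))
  assert_valid_data(data)
  wt <- workload_table(data)
  entropy <- bind_rows(
    entropy_table(wt, "relative_workload", config$supergroups),
    entropy_table(wt, "reserve", config$supergroups),
    entropy_table(wt, "excess", config$supergroups)
  )
  structure(
    list(
      workload = wt,
      totals = workload_totals(wt),
      entropy = entropy,
      scenarios = evaluate_scenarios(wt, config$thresholds),
      config = config,
      provenance = list(
        source = attr(data, "source"),
        generation_seed = attr(data, "generation")$seed,
        period_days = data$period_days,
        n_employees = nrow(data$roster)
      )
    ),
    class = "workload_report"
  )
}

#' Render an analysis report
#'
#' @param report A `workload_report` from [analyze_workload()].
#' @param format `"text"` for a human-readable report; `"json"` for a
#'   single JSON document; `"csv"` for a named character vector of CSV
#'   texts (`workload`, `entropy`, `scenarios`). JSON and CSV are loss-free
#'   to the configured decimal precision.
#' @return A character scalar (text, json) or named character vector (csv).
#' @export
render_report <- function(report, format = c("text", "json", "csv")) {
  stopifnot(inherits(report, "workload_report"))
  format <- match.arg(format)
  dp <- report$config$decimal_places
  switch(format,
    text = render_text(report, dp),
    json = render_json(report, dp),
    csv = render_csv(report, dp)
  )
}

round_df <- function(df, dp) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = dp)
  df
}

scenarios_flat <- function(scenarios, dp) {
  ev <- purrr::map(scenarios$evidence,
                   ~ tibble::as_tibble(lapply(.x, round, digits = dp)))
  dplyr::bind_cols(scenarios[, c("case_id", "triggered")],
                   bind_rows(ev),
                   scenarios[, "recommendation"])
}

render_text <- function(report, dp) {
  fmt_tbl <- function(df) {
    paste(utils::capture.output(print(as.data.frame(round_df(df, dp)),
                                      row.names = FALSE)),
          collapse = "\n")
  }
  t <- report$totals
  lines <- c(
    "Workload evenness analysis",
    "==========================",
    sprintf("Employees: %d   Period: %d working days",
            report$provenance$n_employees, report$provenance$period_days),
    "",
    "Per-employee workloads (credits)",
    fmt_tbl(report$workload),
    "",
    sprintf("Totals: normative %s, actual %s, difference %s (reserves %s, excess %s)",
            format(t$normative), format(t$actual), format(t$difference),
            format(t$reserve_total), format(t$excess_total)),
    "",
    "Evenness (base-2 Shannon entropy of normalized shares)",
    fmt_tbl(report$entropy),
    "",
    "Decision scenarios",
    ""
  )
  sc <- report$scenarios
  for (i in seq_len(nrow(sc))) {
    ev <- sc$evidence[[i]]
    lines <- c(lines,
      sprintf("Case %d: %s", sc$case_id[i],
              if (sc$triggered[i]) "TRIGGERED" else "not triggered"),
      sprintf("  evidence: %s",
              paste(sprintf("%s=%s", names(ev),
                            format(round(unlist(ev), dp))), collapse = " ")),
      sprintf("  %s", sc$recommendation[i]),
      "")
  }
  paste(lines, collapse = "\n")
}

render_json <- function(report, dp) {
  payload <- list(
    provenance = report$provenance,
    totals = report$totals,
    workload = round_df(report$workload, dp),
    entropy = round_df(report$entropy, dp),
    scenarios = round_df(scenarios_flat(report$scenarios, dp), dp)
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

render_csv <- function(report, dp) {
  as_csv <- function(df) readr::format_csv(round_df(df, dp))
  c(workload = as_csv(report$workload),
    entropy = as_csv(report$entropy),
    scenarios = as_csv(scenarios_flat(report$scenarios, dp)))
}

#' @export
print.workload_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
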