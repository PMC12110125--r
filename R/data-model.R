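#' Assemble a clinic dataset from its four component tables
#'
#' A clinic dataset bundles the four administrative tables the workload model
#' needs, together with the length of the observation period:
#'
#' * `roster` — one row per employee: `employee_id`, `category`
#'   (qualification), `share` (employment share in `(0, 1]`).
#' * `params` — one row per category: `category`, `nominal_day_credits`
#'   (credits per working day at full employment; 1 credit = 1 minute for a
#'   480-credit, 8-hour day), `effective_fraction` (share of nominal time
#'   spent directly on service provision, in `(0, 1)`), `daily_loss_fraction`
#'   (expected share lost per day to trips, incapacity, training, in
#'   `[0, 1)`).
#' * `catalog` — one row per (service, category) pair: `service_id`, `name`,
#'   `category`, `credits` (integer time credits the service takes a member
#'   of that category).
#' * `log` — one row per batch of delivered services: `employee_id`,
#'   `service_id`, `count` (integer >= 1), `duration_coefficient` (positive
#'   multiplier on the standard time, default 1; used when a complicated
#'   case took longer than the time-and-motion standard).
#'
#' @param roster,params,catalog,log Data frames with the columns above. `log`
#'   may be `NULL` or empty; a missing `duration_coefficient` column is
#'   filled with 1.
#' @param period_days Number of working days `T` in the analysed period.
#'
#' @return An object of class `clinic_data`: a list with elements `roster`,
#'   `params`, `catalog`, `log` (tibbles) and `period_days`.
#' @seealso [read_clinic_data()], [validate_clinic_data()],
#'   [workload_table()], [dental_clinic_fixture()]
#' @export
#' @examples
#' data <- dental_clinic_fixture()
#' data
clinic_data <- function(roster, params, catalog, log = NULL, period_days) {
  roster <- coerce_table(roster, "roster",
    required = c(employee_id = "character", category = "character",
                 share = "numeric"))
  params <- coerce_table(params, "params",
    required = c(category = "character", nominal_day_credits = "numeric",
                 effective_fraction = "numeric",
                 daily_loss_fraction = "numeric"))
  catalog <- coerce_table(catalog, "catalog",
    required = c(service_id = "character", name = "character",
                 category = "character", credits = "numeric"))
  if (is.null(log) || nrow(as.data.frame(log)) == 0L) {
    log <- tibble(employee_id = character(), service_id = character(),
                  count = numeric(), duration_coefficient = numeric())
  } else {
    log <- as_tibble(as.data.frame(log))
    if (!"duration_coefficient" %in% names(log)) {
      log$duration_coefficient <- 1
    }
    log$duration_coefficient[is.na(log$duration_coefficient)] <- 1
    log <- coerce_table(log, "log",
      required = c(employee_id = "character", service_id = "character",
                   count = "numeric", duration_coefficient = "numeric"))
  }
  if (!is.numeric(period_days) || length(period_days) != 1L ||
      is.na(period_days) || period_days < 0) {
    abort("`period_days` must be a single non-negative number.")
  }
  structure(
    list(roster = roster, params = params, catalog = catalog, log = log,
         period_days = as.integer(period_days)),
    class = "clinic_data"
  )
}

# Check required columns exist and coerce them to the expected mode.
coerce_table <- function(x, what, required) {
  x <- as_tibble(as.data.frame(x))
  missing <- setdiff(names(required), names(x))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  for (col in names(required)) {
    x[[col]] <- switch(required[[col]],
      character = as.character(x[[col]]),
      numeric = as.numeric(x[[col]]))
  }
  x[, names(required)]
}

#' @export
print.clinic_data <- function(x, ...) {
  cat(sprintf(
    "<clinic_data> %d employees, %d categories, %d services, %d log rows, %d working days\n",
    nrow(x$roster), nrow(x$params),
    length(unique(x$catalog$service_id)), nrow(x$log), x$period_days))
  invisible(x)
}

#' Read a clinic dataset from CSV or JSON files
#'
#' Each of the four tables may be a UTF-8 comma-separated file with a header
#' row, or a JSON array of records mirroring the same field names (the format
#' is chosen by file extension, `.json` vs anything else). Column schemas are
#' documented in [clinic_data()].
#'
#' @param roster_path,params_path,catalog_path,log_path Paths to the four
#'   tables. `log_path` may be `NULL` for an empty log.
#' @param period_days Number of working days in the analysed period.
#' @return A [clinic_data()] object. Source paths and their MD5 digests are
#'   attached as the `"source"` attribute for report provenance.
#' @export
read_clinic_data <- function(roster_path, params_path, catalog_path,
                             log_path = NULL, period_days) {
  paths <- c(roster = roster_path, params = params_path,
             catalog = catalog_path,
             if (!is.null(log_path)) c(log = log_path))
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("Input file does not exist: %s", p))
  }
  read_one <- function(path) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      out <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) abort(sprintf(
                        "Failed to parse %s as JSON: %s", path,
                        conditionMessage(e))))
      if (length(out) == 0L) return(tibble())
      as_tibble(out)
    } else {
      tryCatch(
        readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
        error = function(e) abort(sprintf(
          "Failed to parse %s as CSV: %s", path, conditionMessage(e))))
    }
  }
  data <- clinic_data(
    roster = read_one(roster_path),
    params = read_one(params_path),
    catalog = read_one(catalog_path),
    log = if (is.null(log_path)) NULL else read_one(log_path),
    period_days = period_days
  )
  report <- validate_clinic_data(data)
  if (!is_valid(report)) {
    abort(paste0("Dataset failed validation:\n",
                 paste(format_findings(report$errors), collapse = "\n")))
  }
  attr(data, "source") <- tibble(
    table = names(paths), path = unname(paths),
    md5 = unname(tools::md5sum(paths)))
  data
}

#' Write a clinic dataset to four CSV files
#'
#' Inverse of [read_clinic_data()]: writes `roster.csv`, `params.csv`,
#' `catalog.csv` and `log.csv` under `dir` with the schemas documented in
#' [clinic_data()].
#'
#' @param data A [clinic_data()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_clinic_data <- function(data, dir) {
  stopifnot(inherits(data, "clinic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(roster = file.path(dir, "roster.csv"),
             params = file.path(dir, "params.csv"),
             catalog = file.path(dir, "catalog.csv"),
             log = file.path(dir, "log.csv"))
  readr::write_csv(data$roster, paths[["roster"]], progress = FALSE)
  readr::write_csv(data$params, paths[["params"]], progress = FALSE)
  readr::write_csv(data$catalog, paths[["catalog"]], progress = FALSE)
  readr::write_csv(data$log, paths[["log"]], progress = FALSE)
  invisible(paths)
}

#' Validate a clinic dataset
#'
#' Checks the invariants the workload model relies on and returns a report
#' rather than failing, so that all problems can be surfaced at once.
#' Errors (dataset unusable): duplicate employee or parameter rows, employment
#' shares outside `(0, 1]`, missing category parameters, effective fraction
#' not exceeding the daily loss fraction (the normative budget would be
#' non-positive), non-positive day credits, service credits below 1,
#' event counts below 1, non-positive duration coefficients, and log events
#' referencing unknown employees or services or a service with no credit
#' entry for the employee's category. Warnings (dataset usable): employees
#' with no logged events and services never used.
#'
#' @param data A [clinic_data()] object.
#' @return A `validation_report`: list with tibbles `errors` and `warnings`,
#'   each with columns `code`, `message`, `locator`. The dataset is usable
#'   iff `errors` is empty (see [is_valid()]).
#' @export
#' @examples
#' report <- validate_clinic_data(dental_clinic_fixture())
#' is_valid(report)
validate_clinic_data <- function(data) {
  stopifnot(inherits(data, "clinic_data"))
  errors <- list()
  warnings <- list()
  finding <- function(code, message, locator) {
    tibble(code = code, message = message, locator = locator)
  }

  roster <- data$roster
  dup <- roster$employee_id[duplicated(roster$employee_id)]
  for (id in unique(dup)) {
    errors <- c(errors, list(finding(
      "duplicate_id", sprintf("employee_id '%s' appears more than once", id),
      sprintf("roster (%s)", id))))
  }
  bad_share <- which(is.na(roster$share) | roster$share <= 0 | roster$share > 1)
  for (i in bad_share) {
    errors <- c(errors, list(finding(
      "share_range",
      sprintf("share %s outside (0, 1]", format(roster$share[i])),
      sprintf("roster row %d (%s)", i, roster$employee_id[i]))))
  }
  empty_cat <- which(is.na(roster$category) | roster$category == "")
  for (i in empty_cat) {
    errors <- c(errors, list(finding(
      "empty_category", "category must be non-empty",
      sprintf("roster row %d (%s)", i, roster$employee_id[i]))))
  }

  params <- data$params
  dup_par <- params$category[duplicated(params$category)]
  for (cat in unique(dup_par)) {
    errors <- c(errors, list(finding(
      "duplicate_params",
      sprintf("category '%s' parameterized more than once", cat),
      sprintf("params (%s)", cat))))
  }
  for (i in seq_len(nrow(params))) {
    eta <- params$effective_fraction[i]
    lam <- params$daily_loss_fraction[i]
    loc <- sprintf("params row %d (%s)", i, params$category[i])
    if (is.na(params$nominal_day_credits[i]) ||
        params$nominal_day_credits[i] <= 0) {
      errors <- c(errors, list(finding(
        "day_credits", "nominal_day_credits must be positive", loc)))
    }
    if (is.na(eta) || eta <= 0 || eta >= 1) {
      errors <- c(errors, list(finding(
        "effective_fraction", "effective_fraction must lie in (0, 1)", loc)))
    }
    if (is.na(lam) || lam < 0 || lam >= 1) {
      errors <- c(errors, list(finding(
        "loss_fraction", "daily_loss_fraction must lie in [0, 1)", loc)))
    }
    if (!is.na(eta) && !is.na(lam) && eta - lam <= 0) {
      errors <- c(errors, list(finding(
        "non_positive_budget",
        sprintf(
          "non-positive effective budget: effective_fraction %s <= daily_loss_fraction %s",
          format(eta), format(lam)), loc)))
    }
  }
  missing_par <- setdiff(unique(roster$category), params$category)
  for (cat in missing_par[!is.na(missing_par) & missing_par != ""]) {
    errors <- c(errors, list(finding(
      "missing_params", sprintf("no CategoryParams entry for category '%s'", cat),
      sprintf("params (%s)", cat))))
  }

  catalog <- data$catalog
  dup_svc <- duplicated(catalog[, c("service_id", "category")])
  for (i in which(dup_svc)) {
    errors <- c(errors, list(finding(
      "duplicate_catalog",
      sprintf("duplicate credit entry for service '%s', category '%s'",
              catalog$service_id[i], catalog$category[i]),
      sprintf("catalog row %d", i))))
  }
  bad_credit <- which(is.na(catalog$credits) | catalog$credits < 1)
  for (i in bad_credit) {
    errors <- c(errors, list(finding(
      "credit_range", "service credits must be at least 1",
      sprintf("catalog row %d (%s)", i, catalog$service_id[i]))))
  }

  log <- data$log
  cat_of <- stats::setNames(roster$category, roster$employee_id)
  for (i in seq_len(nrow(log))) {
    loc <- sprintf("log row %d", i)
    emp <- log$employee_id[i]
    svc <- log$service_id[i]
    if (is.na(log$count[i]) || log$count[i] < 1 ||
        log$count[i] != round(log$count[i])) {
      errors <- c(errors, list(finding(
        "event_count", sprintf("count must be an integer >= 1, got %s",
                               format(log$count[i])), loc)))
    }
    if (is.na(log$duration_coefficient[i]) || log$duration_coefficient[i] <= 0) {
      errors <- c(errors, list(finding(
        "duration_coefficient", "duration_coefficient must be positive", loc)))
    }
    if (!emp %in% roster$employee_id) {
      errors <- c(errors, list(finding(
        "unknown_employee", sprintf("employee '%s' is not in the roster", emp),
        loc)))
    } else if (!svc %in% catalog$service_id) {
      errors <- c(errors, list(finding(
        "unknown_service", sprintf("service '%s' is not in the catalog", svc),
        loc)))
    } else {
      svc_cats <- catalog$category[catalog$service_id == svc]
      if (!cat_of[[emp]] %in% svc_cats) {
        errors <- c(errors, list(finding(
          "category_service_mismatch",
          sprintf("service '%s' has no credit entry for category '%s' (employee '%s')",
                  svc, cat_of[[emp]], emp), loc)))
      }
    }
  }

  idle <- setdiff(roster$employee_id, log$employee_id)
  for (id in idle) {
    warnings <- c(warnings, list(finding(
      "idle_employee", sprintf("employee '%s' has no logged events", id),
      sprintf("roster (%s)", id))))
  }
  unused <- setdiff(unique(catalog$service_id), log$service_id)
  for (id in unused) {
    warnings <- c(warnings, list(finding(
      "unused_service", sprintf("service '%s' never appears in the log", id),
      sprintf("catalog (%s)", id))))
  }

  empty_findings <- tibble(code = character(), message = character(),
                           locator = character())
  structure(
    list(errors = if (length(errors)) bind_rows(errors) else empty_findings,
         warnings = if (length(warnings)) bind_rows(warnings) else empty_findings),
    class = "validation_report"
  )
}

#' Is a validated dataset usable?
#'
#' @param report A `validation_report` from [validate_clinic_data()].
#' @return `TRUE` iff the report carries no errors (warnings are allowed).
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report$errors) == 0L
}

format_findings <- function(findings) {
  if (nrow(findings) == 0L) return(character())
  sprintf("  [%s] %s — %s", findings$code, findings$message, findings$locator)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors) > 0L) {
    cat("Errors:\n")
    cat(format_findings(x$errors), sep = "\n")
    cat("\n")
  }
  if (nrow(x$warnings) > 0L) {
    cat("Warnings:\n")
    cat(format_findings(x$warnings), sep = "\n")
    cat("\n")
  }
  invisible(x)
}

# Stop unless the dataset validates cleanly.
assert_valid_data <- function(data) {
  report <- validate_clinic_data(data)
  if (!is_valid(report)) {
    abort(paste0("Dataset failed validation:\n",
                 paste(format_findings(report$errors), collapse = "\n")))
  }
  invisible(data)
}
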