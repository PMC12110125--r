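#' Effective service capacity of one employee, per working day
#'
#' The credits an employee can devote directly to service provision in one
#' working day: `nominal_day_credits * share * effective_fraction`. The
#' effective fraction excludes documentation, hand-overs and similar
#' non-service time.
#'
#' @param params A single category's parameter row (list or one-row data
#'   frame with `nominal_day_credits`, `effective_fraction`,
#'   `daily_loss_fraction`).
#' @param share Employment share in `(0, 1]`.
#' @return Credits per working day.
#' @seealso [lost_day_credits()], [normative_workload()]
#' @export
#' @examples
#' p <- list(nominal_day_credits = 480, effective_fraction = 0.75,
#'           daily_loss_fraction = 0.10)
#' effective_day_credits(p, share = 1)  # 360
effective_day_credits <- function(params, share) {
  check_share(share)
  params$nominal_day_credits * share * params$effective_fraction
}

#' Expected working-time loss of one employee, per working day
#'
#' Average credits lost per working day to business trips, temporary
#' incapacity, training and the like:
#' `nominal_day_credits * share * daily_loss_fraction`. The loss fraction is
#' a per-category constant identified from institutional statistics and
#' staff surveys.
#'
#' @inheritParams effective_day_credits
#' @return Credits lost per working day.
#' @export
lost_day_credits <- function(params, share) {
  check_share(share)
  params$nominal_day_credits * share * params$daily_loss_fraction
}

check_share <- function(share) {
  if (any(is.na(share) | share <= 0 | share > 1)) {
    abort("`share` must lie in (0, 1].")
  }
  invisible(share)
}

#' Normative workload over a period, in time credits
#'
#' The credits an employee can devote to service delivery over `period_days`
#' working days while maintaining service quality: the per-day effective
#' capacity minus the per-day expected loss, times the number of days,
#' i.e. `nominal_day_credits * share * (effective_fraction -
#' daily_loss_fraction) * period_days`.
#'
#' @inheritParams effective_day_credits
#' @param period_days Number of working days in the period (>= 0).
#' @return Normative workload in credits.
#' @export
#' @examples
#' surgeon <- list(nominal_day_credits = 480, effective_fraction = 0.50,
#'                 daily_loss_fraction = 0.15)
#' normative_workload(surgeon, share = 1, period_days = 5)  # 840
normative_workload <- function(params, share, period_days) {
  check_share(share)
  if (any(period_days < 0)) abort("`period_days` must be non-negative.")
  margin <- params$effective_fraction - params$daily_loss_fraction
  if (any(margin <= 0)) {
    abort("non-positive effective budget: effective_fraction must exceed daily_loss_fraction.")
  }
  # Single product keeps decimal parameter values (0.70 - 0.10, ...) from
  # accumulating binary representation error across separate phi/chi terms.
  params$nominal_day_credits * share * margin * period_days
}

#' Actual workload of one employee from the service log
#'
#' Sums, over the employee's log events, the catalog credits of the service
#' for the employee's category times the event count and the event's
#' duration coefficient. The coefficient scales the standard time when a
#' complicated case made a service run longer (or shorter) than the
#' time-and-motion standard.
#'
#' @param catalog Service catalog tibble (`service_id`, `category`,
#'   `credits`, one row per pair).
#' @param log Service log tibble (`employee_id`, `service_id`, `count`,
#'   `duration_coefficient`).
#' @param employee_id The employee to accumulate.
#' @param category That employee's category (used for the credit lookup).
#' @return Actual workload in credits (0 for an employee with no events).
#' @export
#' @examples
#' data <- dental_clinic_fixture()
#' actual_workload(data$catalog, data$log, "Emp-4", "Surgeon")  # 1650
actual_workload <- function(catalog, log, employee_id, category) {
  events <- log[log$employee_id == employee_id, , drop = FALSE]
  if (nrow(events) == 0L) return(0)
  credit_of <- catalog[catalog$category == category, , drop = FALSE]
  idx <- match(events$service_id, credit_of$service_id)
  if (anyNA(idx)) {
    missing <- unique(events$service_id[is.na(idx)])
    abort(sprintf(
      "service(s) %s have no credit entry for category '%s' (employee '%s')",
      paste(sprintf("'%s'", missing), collapse = ", "), category, employee_id))
  }
  sum(credit_of$credits[idx] * events$count * events$duration_coefficient)
}

#' Relative workload
#'
#' The ratio of actual to normative workload. A value of 1 means the
#' employee is fully and properly loaded; above 1, overloaded beyond the
#' quality-preserving norm; below 1, underloaded with free capacity.
#'
#' @param actual Actual workload in credits (>= 0).
#' @param normative Normative workload in credits (> 0).
#' @return `actual / normative`.
#' @export
relative_workload <- function(actual, normative) {
  if (any(normative <= 0)) {
    abort("`normative` must be positive to form a relative workload.")
  }
  actual / normative
}

#' Per-employee workload table
#'
#' Computes, for every roster employee, the normative workload, the actual
#' workload accumulated from the service log, the relative workload, and the
#' split of their difference into a free-time reserve (positive part of
#' normative minus actual) and excess work (positive part of actual minus
#' normative). Exactly one of reserve and excess is nonzero for any
#' employee, and summed over employees the reserves minus the excesses equal
#' the normative minus the actual total.
#'
#' @param data A [clinic_data()] object that validates cleanly.
#' @return A tibble with one row per employee and columns `employee_id`,
#'   `category`, `share`, `normative`, `actual`, `relative`, `reserve`,
#'   `excess`. Values are exact reals; rounding is left to report rendering.
#' @seealso [workload_totals()], [entropy_table()]
#' @export
#' @examples
#' wt <- workload_table(dental_clinic_fixture())
#' workload_totals(wt)
workload_table <- function(data) {
  stopifnot(inherits(data, "clinic_data"))
  assert_valid_data(data)
  roster <- data$roster
  params <- data$params
  idx <- match(roster$category, params$category)
  nb <- normative_workload(params[idx, ], roster$share, data$period_days)
  rb <- purrr::map2_dbl(roster$employee_id, roster$category,
                        ~ actual_workload(data$catalog, data$log, .x, .y))
  tibble(
    employee_id = roster$employee_id,
    category = roster$category,
    share = roster$share,
    normative = nb,
    actual = rb,
    relative = relative_workload(rb, nb),
    reserve = pmax(nb - rb, 0),
    excess = pmax(rb - nb, 0)
  )
}

#' Totals of a workload table
#'
#' @param wt A workload table from [workload_table()].
#' @return A named list: `normative` (sum of normative workloads, the
#'   institution's capacity over the period), `actual` (credits actually
#'   worked), `difference` (`normative - actual`; positive means net free
#'   capacity), `reserve_total` and `excess_total` (sums of the per-employee
#'   positive parts).
#' @export
workload_totals <- function(wt) {
  list(
    normative = sum(wt$normative),
    actual = sum(wt$actual),
    difference = sum(wt$normative) - sum(wt$actual),
    reserve_total = sum(wt$reserve),
    excess_total = sum(wt$excess)
  )
}
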