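#' Specification for a simulated clinic
#'
#' Describes a synthetic institution for the generator: its staff
#' composition, a service catalog size and credit range, and the workload
#' regime to emulate — the mean relative workload the staff should realize
#' and how widely individual workloads spread around it. The defaults mirror
#' the bundled dental clinic's composition (5 medical categories, 20 staff,
#' 480-credit day, 5-day week) with a balanced regime (mean relative load 1)
#' and a moderate spread of 0.2.
#'
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param categories Tibble with one row per category: `category`,
#'   `nominal_day_credits`, `effective_fraction`, `daily_loss_fraction`,
#'   `n_employees`, and a `share_choices` list-column of admissible
#'   employment shares.
#' @param n_services Number of catalog services, spread round-robin over
#'   categories (at least one per category).
#' @param credit_range Integer `c(min, max)` range the per-service time
#'   credits are drawn from; must fit within one nominal working day.
#' @param target_mean_relative_load Mean relative workload to aim for
#'   (1 = balanced, > 1 overloaded institution, < 1 underloaded).
#' @param load_dispersion Standard deviation of the per-employee target
#'   relative workloads (0 = everyone at the mean).
#' @param period_days Working days in the simulated period.
#' @return A `clinic_spec` list.
#' @seealso [generate_clinic()]
#' @export
clinic_spec <- function(seed = 1L,
                        categories = default_clinic_categories(),
                        n_services = 10L,
                        credit_range = c(5L, 30L),
                        target_mean_relative_load = 1,
                        load_dispersion = 0.2,
                        period_days = 5L) {
  categories <- as_tibble(categories)
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    all(c("category", "nominal_day_credits", "effective_fraction",
          "daily_loss_fraction", "n_employees", "share_choices") %in%
          names(categories)),
    all(categories$n_employees >= 1L),
    length(credit_range) == 2L, credit_range[1] >= 1,
    credit_range[1] <= credit_range[2],
    is.finite(load_dispersion), load_dispersion >= 0,
    target_mean_relative_load > 0,
    period_days >= 1
  )
  if (n_services < nrow(categories)) {
    abort("`n_services` must be at least the number of categories (every category needs a service).")
  }
  if (credit_range[2] > min(categories$nominal_day_credits)) {
    abort("`credit_range` exceeds the nominal day budget: no service may take longer than one working day.")
  }
  structure(
    list(seed = as.integer(seed), categories = categories,
         n_services = as.integer(n_services),
         credit_range = as.integer(credit_range),
         target_mean_relative_load = target_mean_relative_load,
         load_dispersion = load_dispersion,
         period_days = as.integer(period_days)),
    class = "clinic_spec"
  )
}

#' Default staff composition for simulated clinics
#'
#' The bundled dental clinic's composition: 2 orthodontists, 2 surgeons,
#' 4 therapists, 2 hygienists and 10 nurses with their measured
#' effective-time and daily-loss fractions, employment shares drawn from
#' quarter-time steps.
#'
#' @return A tibble suitable for the `categories` field of [clinic_spec()].
#' @export
default_clinic_categories <- function() {
  tibble(
    category = c("Orthodontist", "Surgeon", "Therapist", "Hygienist", "Nurse"),
    nominal_day_credits = 480,
    effective_fraction = c(0.75, 0.50, 0.70, 0.80, 0.80),
    daily_loss_fraction = c(0.10, 0.15, 0.10, 0.05, 0.05),
    n_employees = c(2L, 2L, 4L, 2L, 10L),
    share_choices = list(c(0.25, 0.5, 0.75, 1))
  )
}

#' Generate a synthetic clinic dataset
#'
#' Draws a roster, catalog and service log realizing a target workload
#' regime. Per-employee target relative workloads are drawn from a normal
#' distribution with the spec's mean and dispersion, truncated at zero
#' (degenerate at the mean for zero dispersion). Event counts are then
#' back-solved against the category's services: the desired actual workload
#' is split evenly over the services, counts are floored for all but the
#' cheapest service, and the cheapest service absorbs the remainder by
#' rounding — so the only slack between target and realized workload is the
#' sub-credit rounding residue. Zero-count events are omitted.
#'
#' @param spec A [clinic_spec()].
#' @return A validating [clinic_data()] object. The attribute
#'   `"generation"` carries a tibble of per-employee `target_relative`,
#'   `realized_relative` and `residue` (credits), plus the seed, for
#'   calibration checks.
#' @export
#' @examples
#' data <- generate_clinic(clinic_spec(seed = 7, load_dispersion = 0))
#' range(workload_table(data)$relative)
generate_clinic <- function(spec) {
  stopifnot(inherits(spec, "clinic_spec"))
  withr::with_seed(spec$seed, generate_clinic_impl(spec))
}

generate_clinic_impl <- function(spec) {
  cats <- spec$categories
  params <- cats[, c("category", "nominal_day_credits", "effective_fraction",
                     "daily_loss_fraction")]

  n_total <- sum(cats$n_employees)
  roster <- tibble(
    employee_id = sprintf("Emp-%d", seq_len(n_total)),
    category = rep(cats$category, cats$n_employees),
    share = unlist(purrr::map2(cats$share_choices, cats$n_employees,
                               ~ sample(.x, .y, replace = TRUE)))
  )

  svc_cat <- rep_len(cats$category, spec$n_services)
  catalog <- tibble(
    service_id = sprintf("svc-%02d", seq_len(spec$n_services)),
    name = sprintf("Simulated service %d", seq_len(spec$n_services)),
    category = svc_cat,
    credits = sample(seq(spec$credit_range[1], spec$credit_range[2]),
                     spec$n_services, replace = TRUE)
  )

  idx <- match(roster$category, params$category)
  nb <- normative_workload(params[idx, ], roster$share, spec$period_days)
  targets <- draw_targets(n_total, spec$target_mean_relative_load,
                          spec$load_dispersion)
  desired <- targets * nb
  if (spec$credit_range[1] > 2 * min(desired[desired > 0], Inf)) {
    abort("Infeasible spec: the cheapest service's credits exceed twice the smallest desired workload; integer counts cannot approach the target load. Narrow `credit_range` or raise the target.")
  }

  log_rows <- purrr::map(seq_len(n_total), function(i) {
    svcs <- catalog[catalog$category == roster$category[i], , drop = FALSE]
    svcs <- svcs[order(svcs$credits, decreasing = TRUE), , drop = FALSE]
    k <- nrow(svcs)
    split <- desired[i] / k
    counts <- numeric(k)
    if (k > 1) counts[seq_len(k - 1)] <- floor(split / svcs$credits[seq_len(k - 1)])
    remaining <- desired[i] - sum(counts * svcs$credits)
    counts[k] <- round(remaining / svcs$credits[k])
    keep <- counts >= 1
    tibble(employee_id = roster$employee_id[i],
           service_id = svcs$service_id[keep],
           count = counts[keep],
           duration_coefficient = 1)
  })
  log <- bind_rows(log_rows)

  data <- clinic_data(roster, params, catalog, log,
                      period_days = spec$period_days)
  assert_valid_data(data)
  realized <- workload_table(data)
  attr(data, "generation") <- list(
    seed = spec$seed,
    calibration = tibble(
      employee_id = roster$employee_id,
      target_relative = targets,
      realized_relative = realized$relative,
      residue = realized$actual - desired
    )
  )
  data
}

# Normal draws truncated at zero; degenerate at the mean for sd = 0.
draw_targets <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  for (attempt in 1:1000) {
    out[todo] <- rnorm(length(todo), mean, sd)
    todo <- which(out <= 0)
    if (length(todo) == 0L) return(out)
  }
  abort("Infeasible spec: could not draw positive target workloads; `load_dispersion` is too large relative to the mean.")
}
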