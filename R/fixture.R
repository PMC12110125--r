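#' Bundled dental-clinic example dataset
#'
#' A fully worked example: the 20 medical employees of a private dental
#' clinic (2 orthodontists, 2 surgeons, 4 therapists, 2 hygienists,
#' 10 nurses) observed over one 5-day workweek, with per-category
#' effective-time and daily-loss fractions from the clinic's time-and-motion
#' study and a 480-credit (8-hour, 1 credit = 1 minute) nominal working day.
#'
#' The clinic's real 24-service catalog is not distributed with the package;
#' the bundled catalog is synthetic — one representative service per
#' category with a small integer credit value — and the service log's event
#' counts are back-solved so that every employee's actual workload equals
#' the clinic's recorded value exactly. All downstream numbers (workload
#' table, totals, entropy tables, scenario evidence) are therefore those of
#' the real clinic week.
#'
#' @return A [clinic_data()] object with 20 employees, 5 categories and
#'   `period_days = 5`. Normative capacity totals 21270 credits against
#'   19852 credits actually worked.
#' @export
#' @examples
#' wt <- workload_table(dental_clinic_fixture())
#' sum(wt$normative)  # 21270
#' sum(wt$actual)     # 19852
dental_clinic_fixture <- function() {
  roster <- tibble(
    employee_id = paste0("Emp-", 1:20),
    category = c("Orthodontist", "Orthodontist", "Surgeon", "Surgeon",
                 "Therapist", "Therapist", "Therapist", "Therapist",
                 "Hygienist", "Hygienist", rep("Nurse", 10)),
    share = c(1.00, 0.75, 0.50, 1.00, 0.75, 1.00, 0.50, 1.00, 0.75, 1.00,
              0.50, 0.25, 0.75, 0.50, 0.75, 0.50, 0.50, 0.75, 0.25, 0.50)
  )
  params <- tibble(
    category = c("Orthodontist", "Surgeon", "Therapist", "Hygienist", "Nurse"),
    nominal_day_credits = 480,
    effective_fraction = c(0.75, 0.50, 0.70, 0.80, 0.80),
    daily_loss_fraction = c(0.10, 0.15, 0.10, 0.05, 0.05)
  )
  # Synthetic stand-in catalog: one service per category, credit value the
  # gcd of the category's recorded actual workloads so counts stay integer.
  catalog <- tibble(
    service_id = c("svc-ortho", "svc-surg", "svc-ther", "svc-hyg", "svc-nurse"),
    name = c("Orthodontic appointment (synthetic)",
             "Surgical procedure unit (synthetic)",
             "Therapeutic treatment (synthetic)",
             "Hygiene session (synthetic)",
             "Nursing care unit (synthetic)"),
    category = c("Orthodontist", "Surgeon", "Therapist", "Hygienist", "Nurse"),
    credits = c(10, 5, 50, 25, 4)
  )
  actual <- c(2050, 1160, 655, 1650, 1250, 1600, 600, 1450, 1050, 1475,
              532, 376, 928, 884, 884, 532, 532, 928, 408, 908)
  svc_of <- stats::setNames(catalog$service_id, catalog$category)
  credit_of <- stats::setNames(catalog$credits, catalog$category)
  log <- tibble(
    employee_id = roster$employee_id,
    service_id = unname(svc_of[roster$category]),
    count = actual / unname(credit_of[roster$category]),
    duration_coefficient = 1
  )
  clinic_data(roster, params, catalog, log, period_days = 5)
}
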