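# Independent oracles and small builders shared across the suite.

# Brute-force Shannon entropy in bits: explicit normalization, term-by-term
# Kahan-compensated summation over ascending terms, natural log rescaled.
# Deliberately shares no code path with shannon_entropy().
entropy_oracle <- function(values, drop_zeros = FALSE) {
  if (drop_zeros) values <- values[values != 0]
  if (length(values) == 0 || sum(values) == 0) return(0)
  p <- values / sum(values)
  terms <- sort(vapply(p, function(x) if (x > 0) -x * log(x) / log(2) else 0,
                       numeric(1)))
  total <- 0
  comp <- 0
  for (t in terms) {
    y <- t - comp
    s <- total + y
    comp <- (s - total) - y
    total <- s
  }
  total
}

# Event-by-event accumulation of an employee's actual workload.
actual_oracle <- function(catalog, log, employee_id, category) {
  total <- 0
  for (i in seq_len(nrow(log))) {
    if (log$employee_id[i] != employee_id) next
    row <- which(catalog$service_id == log$service_id[i] &
                   catalog$category == category)
    stopifnot(length(row) == 1)
    total <- total + catalog$credits[row] * log$count[i] *
      log$duration_coefficient[i]
  }
  total
}

# A minimal two-category dataset for targeted construction of workload
# patterns: one service per category, credits 10, share 1, 480-credit day.
toy_data <- function(actuals, categories = rep("CatA", length(actuals)),
                     eta = 0.5, lambda = 0.1, period_days = 5) {
  n <- length(actuals)
  roster <- tibble::tibble(
    employee_id = sprintf("E%d", seq_len(n)),
    category = categories,
    share = 1
  )
  cats <- unique(categories)
  params <- tibble::tibble(
    category = cats, nominal_day_credits = 480,
    effective_fraction = eta, daily_loss_fraction = lambda
  )
  catalog <- tibble::tibble(
    service_id = paste0("svc-", cats), name = cats,
    category = cats, credits = 10
  )
  keep <- actuals > 0
  log <- tibble::tibble(
    employee_id = roster$employee_id[keep],
    service_id = paste0("svc-", categories[keep]),
    count = actuals[keep] / 10,
    duration_coefficient = 1
  )
  clinic_data(roster, params, catalog, log, period_days = period_days)
}

# Expected fixture columns (the clinic's recorded week).
fixture_normative <- c(1560, 1170, 420, 840, 1080, 1440, 720, 1440, 1350,
                       1800, 900, 450, 1350, 900, 1350, 900, 900, 1350,
                       450, 900)
fixture_actual <- c(2050, 1160, 655, 1650, 1250, 1600, 600, 1450, 1050,
                    1475, 532, 376, 928, 884, 884, 532, 532, 928, 408, 908)
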