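test_that("normalize_shares divides by the retained total", {
  s <- normalize_shares(c(10, 120))
  expect_equal(s$share, c(10, 120) / 130)
  expect_equal(s$share, c(0.076923, 0.923077), tolerance = 1e-5)
  expect_equal(normalize_shares(c(5, 5, 5, 5))$share, rep(0.25, 4))
  dropped <- normalize_shares(c(0, 7, 0, 3), letters[1:4], drop_zeros = TRUE)
  expect_identical(dropped$label, c("b", "d"))
  expect_equal(dropped$share, c(0.7, 0.3))
  expect_identical(nrow(normalize_shares(c(0, 0), drop_zeros = TRUE)), 0L)
  expect_error(normalize_shares(c(-1, 2)), "non-negative")
})

test_that("entropy of the clinic's reserve groups matches the recorded values", {
  expect_equal(shannon_entropy(normalize_shares(c(300, 325))),
               0.998846, tolerance = 1e-5)
  expect_equal(shannon_entropy(normalize_shares(c(10, 120))),
               0.3912436, tolerance = 1e-6)
  nurse_reserves <- c(368, 74, 422, 16, 466, 368, 368, 422, 42)
  expect_equal(shannon_entropy(normalize_shares(nurse_reserves)),
               2.809968, tolerance = 1e-5)
  expect_identical(shannon_entropy(rep(0.25, 4)), 2)
  expect_identical(shannon_entropy(1), 0)
  expect_identical(shannon_entropy(numeric(0)), 0)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("relative entropy rescales to the group maximum, 0 for singletons", {
  expect_equal(relative_entropy_pct(2.809968, 9), 88.644624, tolerance = 1e-4)
  expect_identical(relative_entropy_pct(0, 1), 0)
  expect_identical(relative_entropy_pct(0, 0), 0)
  expect_equal(relative_entropy_pct(2, 4), 100)
})

test_that("fixture reserves and excesses reproduce the clinic's totals", {
  wt <- workload_table(dental_clinic_fixture())
  res <- reserve_credits(wt)
  expect_identical(res$total, 3301)
  expect_identical(sum(res$per_employee$reserve > 0), 13L)
  exc <- excess_credits(wt)
  expect_identical(exc$total, 1883)
  expect_identical(sum(exc$per_employee$excess > 0), 7L)
  surgeons <- wt[wt$category == "Surgeon", ]
  expect_identical(surgeons$excess, c(235, 810))
})

test_that("group summaries reproduce the clinic's reserve evenness table", {
  wt <- workload_table(dental_clinic_fixture())
  check_row <- function(s, n, total, H, pct) {
    expect_identical(s$member_count, n)
    expect_identical(s$total_credits, total)
    expect_equal(s$entropy, H, tolerance = 1e-5)
    expect_equal(s$relative_entropy_pct, pct, tolerance = 1e-3)
  }
  check_row(group_summary(wt, "All Employees", "reserve"),
            13L, 3301, 3.299140, 89.155354)
  check_row(group_summary(wt, "Doctors", "reserve"),
            2L, 130, 0.391244, 39.124356)
  check_row(group_summary(wt, "Orthodontist", "reserve"), 1L, 10, 0, 0)
  check_row(group_summary(wt, "Therapist", "reserve"), 1L, 120, 0, 0)
  check_row(group_summary(wt, "Hygienist", "reserve"),
            2L, 625, 0.998846, 99.884554)
  check_row(group_summary(wt, "Nurse", "reserve"),
            9L, 2546, 2.809968, 88.644624)
})

test_that("group summaries reproduce the clinic's excess evenness table", {
  wt <- workload_table(dental_clinic_fixture())
  check_row <- function(s, n, total, H, pct) {
    expect_identical(s$member_count, n)
    expect_equal(s$total_credits, total)
    expect_equal(s$entropy, H, tolerance = 1e-5)
    expect_equal(s$relative_entropy_pct, pct, tolerance = 1e-3)
  }
  check_row(group_summary(wt, "All Employees", "excess"),
            7L, 1883, 2.092679, 74.542727)
  check_row(group_summary(wt, "Doctors", "excess"),
            6L, 1875, 2.061849, 79.763207)
  check_row(group_summary(wt, "Orthodontist", "excess"), 1L, 490, 0, 0)
  check_row(group_summary(wt, "Surgeon", "excess"),
            2L, 1045, 0.768979, 76.897934)
  check_row(group_summary(wt, "Therapist", "excess"),
            3L, 340, 1.161378, 73.274824)
  check_row(group_summary(wt, "Nurse", "excess"), 1L, 8, 0, 0)
  expect_error(group_summary(wt, "Dermatologist", "excess"), "Unknown group")
})

test_that("relative-workload evenness keeps all members and matches the oracle", {
  wt <- workload_table(dental_clinic_fixture())
  s <- group_summary(wt, "All Employees", "relative_workload")
  expect_identical(s$member_count, 20L)
  expect_true(is.na(s$total_credits))
  expect_equal(s$entropy, entropy_oracle(wt$relative), tolerance = 1e-10)
  # uniform pair: exactly one bit
  pair <- toy_data(c(960, 960))
  expect_equal(group_summary(workload_table(pair), "All Employees",
                             "relative_workload")$entropy, 1)
})

test_that("entropy is bounded by log2(n), with equality exactly at uniformity", {
  withr::local_seed(99)
  for (trial in 1:50) {
    n <- sample(2:20, 1)
    v <- stats::runif(n, 0.01, 10)
    h <- shannon_entropy(normalize_shares(v))
    expect_gte(h, 0)
    expect_lte(h, log2(n) + 1e-9)
  }
  expect_equal(shannon_entropy(normalize_shares(rep(7, 16))), 4)
  expect_lt(shannon_entropy(normalize_shares(c(1, 1, 1, 2))), 2)
})

test_that("entropy is invariant to permutation and positive rescaling", {
  withr::local_seed(7)
  v <- stats::runif(12, 0.1, 5)
  h <- shannon_entropy(normalize_shares(v))
  expect_equal(shannon_entropy(normalize_shares(sample(v))), h)
  expect_equal(shannon_entropy(normalize_shares(v * 1e3)), h)
  expect_equal(shannon_entropy(normalize_shares(v * 1e-4)), h)
})

test_that("adding a zero-quantity member changes nothing under drop_zeros", {
  v <- c(3, 9, 1)
  with_zero <- shannon_entropy(normalize_shares(c(v, 0), drop_zeros = TRUE))
  expect_identical(with_zero,
                   shannon_entropy(normalize_shares(v, drop_zeros = TRUE)))
})

test_that("entropy agrees with a compensated-summation oracle on random vectors", {
  withr::local_seed(20260928)
  for (trial in 1:1000) {
    n <- sample(1:20, 1)
    v <- stats::rexp(n) * 10^sample(-2:3, 1)
    expect_equal(shannon_entropy(normalize_shares(v)), entropy_oracle(v),
                 tolerance = 1e-10)
  }
})
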