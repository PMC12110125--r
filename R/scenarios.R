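#' Thresholds for the managerial decision scenarios
#'
#' The scenario rules compare entropies with "close to maximum" / "close to
#' zero" and workload totals with "much larger". These are qualitative
#' judgements; the engine makes them operational with three configurable
#' cut-offs:
#'
#' * `near_max_fraction` — `H` counts as near its maximum iff
#'   `H >= near_max_fraction * Hmax` (default 0.90).
#' * `near_zero_fraction` — `H` counts as near zero iff
#'   `H <= near_zero_fraction * Hmax` (default 0.25). Measuring against the
#'   group's own maximum keeps the judgement comparable across group sizes.
#' * `imbalance_ratio` — one workload total dominates another iff it is at
#'   least `imbalance_ratio` times larger (default 1.15).
#'
#' Reports always print the underlying evidence so users can re-judge a
#' borderline call under their own cut-offs.
#'
#' @param near_max_fraction Fraction of `Hmax` above which entropy is "near
#'   maximal", in `(0, 1)`.
#' @param near_zero_fraction Fraction of `Hmax` below which entropy is "near
#'   zero", in `(0, 1)`; must be below `near_max_fraction`.
#' @param imbalance_ratio Ratio above which one total dominates, > 1.
#' @return A `scenario_thresholds` list.
#' @export
scenario_thresholds <- function(near_max_fraction = 0.90,
                                near_zero_fraction = 0.25,
                                imbalance_ratio = 1.15) {
  stopifnot(near_max_fraction > 0, near_max_fraction < 1,
            near_zero_fraction > 0, near_zero_fraction < 1,
            near_zero_fraction < near_max_fraction,
            imbalance_ratio > 1)
  structure(list(near_max_fraction = near_max_fraction,
                 near_zero_fraction = near_zero_fraction,
                 imbalance_ratio = imbalance_ratio),
            class = "scenario_thresholds")
}

scenario_recommendations <- c(
  "1" = "Workload is evenly spread but the actual total far exceeds the normative capacity: most employees are significantly overloaded. Consider hiring additional staff.",
  "2" = "Workload is evenly spread but the normative capacity far exceeds the actual total: employees are systematically underloaded. The institution has capacity to offer new services or attract more clients.",
  "3" = "Free-time reserves are concentrated and large: at least one employee is significantly underloaded. If needed, that employee can be relieved and their duties redistributed to reduce the burden on others.",
  "4" = "Both free-time reserves and excess work are concentrated in few hands: redistribute responsibilities within the group to balance workload and relieve the overloaded individuals."
)

#' Evaluate the four managerial decision scenarios
#'
#' Classifies a group of employees (the whole institution or any subset)
#' against four decision cases, using the workload-distribution entropy
#' `H`, the reserve entropy `H_R`, the excess entropy `H_O` and the
#' workload totals:
#'
#' * Case 1 (hire): `H` near maximal and the actual total dominates the
#'   normative total — an even, general overload.
#' * Case 2 (expand): `H` near maximal and the normative total dominates the
#'   actual total — an even, general underload.
#' * Case 3 (relieve): `H_R` near zero and the total reserve is at least the
#'   mean normative workload — the free time concentrated in few hands is
#'   enough to free up a whole position.
#' * Case 4 (rebalance): both `H_R` and `H_O` near zero — reserves and
#'   excesses sit with few individuals, so duties can be shifted between
#'   them.
#'
#' `H` is computed over all group members' relative workloads; `H_R` and
#' `H_O` over the members with nonzero reserve / excess, each against its
#' own maximum (see [scenario_thresholds()]). The findings are advisory:
#' flags plus evidence, never an action.
#'
#' @param wt A workload table from [workload_table()], already restricted to
#'   the scope of interest (whole institution or one group).
#' @param thresholds A [scenario_thresholds()] object.
#' @return A tibble with one row per case: `case_id`, `triggered`,
#'   `recommendation`, and an `evidence` list-column of named indicator
#'   values (`H`, `H_max`, `sum_NB`, `sum_RB`, `H_R`, `H_max_R`, `H_O`,
#'   `H_max_O`, `R_total`, `O_total`, `mean_NB`).
#' @export
#' @examples
#' wt <- workload_table(dental_clinic_fixture())
#' evaluate_scenarios(wt)
evaluate_scenarios <- function(wt, thresholds = scenario_thresholds()) {
  stopifnot(inherits(thresholds, "scenario_thresholds"))
  if (nrow(wt) == 0L) abort("Cannot evaluate scenarios over an empty group.")

  h_load <- shannon_entropy(normalize_shares(wt$relative, wt$employee_id))
  h_load_max <- if (nrow(wt) > 1) log2(nrow(wt)) else 0
  res <- normalize_shares(wt$reserve, wt$employee_id, drop_zeros = TRUE)
  exc <- normalize_shares(wt$excess, wt$employee_id, drop_zeros = TRUE)
  h_r <- shannon_entropy(res)
  h_o <- shannon_entropy(exc)
  h_r_max <- if (nrow(res) > 1) log2(nrow(res)) else 0
  h_o_max <- if (nrow(exc) > 1) log2(nrow(exc)) else 0
  sum_nb <- sum(wt$normative)
  sum_rb <- sum(wt$actual)
  r_total <- sum(wt$reserve)
  o_total <- sum(wt$excess)
  mean_nb <- sum_nb / nrow(wt)

  evidence <- list(
    H = h_load, H_max = h_load_max, sum_NB = sum_nb, sum_RB = sum_rb,
    H_R = h_r, H_max_R = h_r_max, H_O = h_o, H_max_O = h_o_max,
    R_total = r_total, O_total = o_total, mean_NB = mean_nb)

  near_max <- h_load >= thresholds$near_max_fraction * h_load_max &&
    h_load_max > 0
  r_near_zero <- h_r <= thresholds$near_zero_fraction * h_r_max
  o_near_zero <- h_o <= thresholds$near_zero_fraction * h_o_max

  triggered <- c(
    near_max && sum_rb >= thresholds$imbalance_ratio * sum_nb,
    near_max && sum_nb >= thresholds$imbalance_ratio * sum_rb,
    r_near_zero && r_total >= mean_nb,
    r_near_zero && o_near_zero
  )

  tibble(
    case_id = 1:4,
    triggered = triggered,
    recommendation = unname(scenario_recommendations),
    evidence = rep(list(evidence), 4)
  )
}
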