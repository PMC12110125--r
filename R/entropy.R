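#' Normalize non-negative quantities into shares
#'
#' Divides each value by the total over the retained members, giving the
#' share vector that Shannon entropy is evaluated on. With
#' `drop_zeros = TRUE`, zero-valued members are removed before normalizing —
#' the convention used for free-time reserves and excess credits, where only
#' employees actually holding the quantity count towards the group. Without
#' it zeros are retained and contribute nothing to the entropy.
#'
#' @param values Non-negative numeric vector.
#' @param labels Optional labels (e.g. employee ids), same length as
#'   `values`.
#' @param drop_zeros Remove zero entries before normalizing?
#' @return A tibble with columns `label` and `share`; shares sum to 1 unless
#'   all values are zero, in which case the tibble is empty.
#' @export
#' @examples
#' normalize_shares(c(10, 120))
#' normalize_shares(c(0, 7, 0, 3), letters[1:4], drop_zeros = TRUE)
normalize_shares <- function(values, labels = NULL, drop_zeros = FALSE) {
  if (any(is.na(values) | values < 0)) {
    abort("`values` must be non-negative and free of NA.")
  }
  if (is.null(labels)) labels <- as.character(seq_along(values))
  stopifnot(length(labels) == length(values))
  if (drop_zeros) {
    keep <- values > 0
    values <- values[keep]
    labels <- labels[keep]
  }
  total <- sum(values)
  if (length(values) == 0L || total == 0) {
    return(tibble(label = character(), share = numeric()))
  }
  tibble(label = as.character(labels), share = values / total)
}

#' Base-2 Shannon entropy of a share vector
#'
#' Computes `-sum(s * log2(s))` with the convention `0 * log2(0) = 0`. For a
#' group of `n` members the value lies in `[0, log2(n)]`, reaching the
#' maximum exactly when all shares are equal — hence its use as an evenness
#' score for workload, reserve and excess distributions.
#'
#' @param shares Either a numeric vector of non-negative shares summing to 1
#'   or a tibble from [normalize_shares()].
#' @return Entropy in bits; 0 for an empty vector.
#' @export
#' @examples
#' shannon_entropy(normalize_shares(c(10, 120)))  # 0.391244 bits
#' shannon_entropy(rep(0.25, 4))                  # 2 bits
shannon_entropy <- function(shares) {
  if (is.data.frame(shares)) shares <- shares$share
  if (length(shares) == 0L) return(0)
  if (any(is.na(shares) | shares < 0)) {
    abort("`shares` must be non-negative and free of NA.")
  }
  if (abs(sum(shares) - 1) > 1e-9) {
    abort("`shares` must sum to 1; use normalize_shares() first.")
  }
  nz <- shares[shares > 0]
  -sum(nz * log2(nz))
}

#' Entropy as a percentage of the group maximum
#'
#' Rescales an entropy to `100 * H / log2(n)`, the evenness score reported
#' alongside raw entropies. Groups of one member (or none) have no defined
#' maximum and report 0.
#'
#' @param entropy Entropy in bits (>= 0).
#' @param member_count Number of group members the entropy was computed over.
#' @return Percentage in `[0, 100]`.
#' @export
relative_entropy_pct <- function(entropy, member_count) {
  if (any(entropy < 0) || any(member_count < 0)) {
    abort("`entropy` and `member_count` must be non-negative.")
  }
  ifelse(member_count > 1, 100 * entropy / log2(member_count), 0)
}

#' Free-time reserves per employee
#'
#' The reserve is the positive part of normative minus actual workload:
#' unused capacity held only by underloaded employees.
#'
#' @param wt A workload table from [workload_table()].
#' @return A list: `per_employee`, a tibble of `employee_id` and `reserve`;
#'   and `total`, the institution's redistribution potential in credits.
#' @export
reserve_credits <- function(wt) {
  list(per_employee = wt[, c("employee_id", "reserve")],
       total = sum(wt$reserve))
}

#' Excess credits per employee
#'
#' The positive part of actual minus normative workload: credits worked
#' beyond the quality-preserving norm, held only by overloaded employees.
#'
#' @param wt A workload table from [workload_table()].
#' @return A list: `per_employee`, a tibble of `employee_id` and `excess`;
#'   and `total` in credits.
#' @export
excess_credits <- function(wt) {
  list(per_employee = wt[, c("employee_id", "excess")],
       total = sum(wt$excess))
}

#' Entropy summary of one quantity over one group
#'
#' Evaluates the Shannon evenness of `relative_workload`, `reserve` or
#' `excess` over a group of employees. For reserves and excesses only the
#' members actually holding a nonzero amount count: they define the member
#' count, the total credits and the maximum entropy `log2(n)`. For relative
#' workloads every group member is retained (an idle employee's zero share
#' contributes nothing) and no credit total is reported.
#'
#' @param wt A workload table from [workload_table()].
#' @param group `"All Employees"`, a category name, or a supergroup name
#'   from `supergroups`.
#' @param quantity One of `"relative_workload"`, `"reserve"`, `"excess"`.
#' @param supergroups Named list mapping supergroup names to character
#'   vectors of categories, e.g. the default
#'   `list(Doctors = c("Orthodontist", "Surgeon", "Therapist"))`.
#' @return A one-row tibble: `group`, `quantity`, `member_count`,
#'   `total_credits` (NA for relative workload), `entropy`, `max_entropy`,
#'   `relative_entropy_pct`. An empty group yields `member_count` 0 and
#'   entropy 0.
#' @export
#' @examples
#' wt <- workload_table(dental_clinic_fixture())
#' group_summary(wt, "All Employees", "reserve")
#' group_summary(wt, "Doctors", "excess")
group_summary <- function(wt, group, quantity = c("relative_workload",
                                                  "reserve", "excess"),
                          supergroups = default_supergroups()) {
  quantity <- match.arg(quantity)
  members <- select_group(wt, group, supergroups)
  values <- switch(quantity,
    relative_workload = members$relative,
    reserve = members$reserve,
    excess = members$excess)
  drop <- quantity != "relative_workload"
  shares <- normalize_shares(values, members$employee_id, drop_zeros = drop)
  n <- if (drop) nrow(shares) else nrow(members)
  h <- shannon_entropy(shares)
  tibble(
    group = group,
    quantity = quantity,
    member_count = n,
    total_credits = if (drop) sum(values) else NA_real_,
    entropy = h,
    max_entropy = if (n > 1) log2(n) else 0,
    relative_entropy_pct = relative_entropy_pct(h, n)
  )
}

select_group <- function(wt, group, supergroups) {
  if (identical(group, "All Employees")) return(wt)
  if (group %in% names(supergroups)) {
    return(wt[wt$category %in% supergroups[[group]], , drop = FALSE])
  }
  if (group %in% wt$category) {
    return(wt[wt$category == group, , drop = FALSE])
  }
  abort(sprintf("Unknown group label '%s'.", group))
}

#' Default supergroup taxonomy
#'
#' Maps the "Doctors" supergroup onto the three doctoral specialties of a
#' dental clinic. Supergroups are configuration, not model: pass your own
#' mapping to [group_summary()] or [analysis_config()] for other
#' institutions.
#'
#' @return Named list of character vectors.
#' @export
default_supergroups <- function() {
  list(Doctors = c("Orthodontist", "Surgeon", "Therapist"))
}

#' Entropy summaries for all groups and one quantity
#'
#' Builds the evenness table for one quantity across the whole staff, each
#' supergroup, and each category, in that order — the layout used for
#' reporting free-time-reserve and excess-credit structure.
#'
#' @inheritParams group_summary
#' @param drop_empty Omit groups with no (nonzero) members? The reporting
#'   convention: a category holding no reserve at all simply has no row in
#'   the reserve table.
#' @return A tibble with one [group_summary()] row per group.
#' @export
#' @examples
#' wt <- workload_table(dental_clinic_fixture())
#' entropy_table(wt, "reserve")
entropy_table <- function(wt, quantity = c("relative_workload", "reserve",
                                           "excess"),
                          supergroups = default_supergroups(),
                          drop_empty = TRUE) {
  quantity <- match.arg(quantity)
  groups <- c("All Employees", names(supergroups), unique(wt$category))
  out <- purrr::map(groups, group_summary, wt = wt, quantity = quantity,
                    supergroups = supergroups) %>%
    bind_rows()
  if (drop_empty) out <- out[out$member_count > 0L, , drop = FALSE]
  out
}
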