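#' Monthly animal protein and lipid intake from food-frequency records
#'
#' Converts food-frequency questionnaire (FFQ) portion counts into approximate
#' grams of animal protein and lipid consumed per month (30 days). Daily
#' portions contribute `days_per_month` portions per month and weekly portions
#' `days_per_month / 7`, each multiplied by the grams the food contributes per
#' portion according to the composition table.
#'
#' @param ffq A data frame with columns `child_id`, `food`,
#'   `portions_per_day` and `portions_per_week`.
#' @param composition A data frame with columns `food`,
#'   `protein_g_per_portion` and `lipid_g_per_portion`.
#' @param days_per_month Days in the nominal month (default 30).
#' @return A tibble with one row per child: `child_id`, `protein_g_month`,
#'   `lipid_g_month`.
#' @export
#' @examples
#' ffq <- tibble::tibble(child_id = "c1", food = "egg",
#'                       portions_per_day = 1, portions_per_week = 0)
#' comp <- tibble::tibble(food = "egg",
#'                        protein_g_per_portion = 6, lipid_g_per_portion = 5)
#' compute_monthly_intake(ffq, comp)  # 180 g protein / month
compute_monthly_intake <- function(ffq, composition, days_per_month = 30) {
  needed <- c("child_id", "food", "portions_per_day", "portions_per_week")
  if (!all(needed %in% names(ffq))) {
    gbm_abort(sprintf("`ffq` needs columns: %s", paste(needed, collapse = ", ")),
              "gbm_validation")
  }
  if (any(ffq$portions_per_day < 0 | ffq$portions_per_week < 0, na.rm = TRUE)) {
    gbm_abort("Portion frequencies must be nonnegative.", "gbm_validation")
  }
  unknown <- setdiff(unique(ffq$food), composition$food)
  if (length(unknown) > 0) {
    gbm_abort(sprintf("Food(s) not in the composition table: %s",
                      paste(unknown, collapse = ", ")),
              "gbm_lookup")
  }
  ffq |>
    dplyr::left_join(composition, by = "food") |>
    dplyr::mutate(
      portions_month = days_per_month * .data$portions_per_day +
        (days_per_month / 7) * .data$portions_per_week
    ) |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(
      protein_g_month = sum(.data$portions_month * .data$protein_g_per_portion),
      lipid_g_month   = sum(.data$portions_month * .data$lipid_g_per_portion),
      .groups = "drop"
    ) |>
    tibble::as_tibble()
}

#' Split a cohort into High/Low consumers at the sample mean
#'
#' Children whose intake is strictly above the sample mean are labelled
#' `"H"`; all others (including values exactly at the mean) are `"L"`.
#'
#' @param values Numeric vector of per-child intakes (grams/month).
#' @return A factor of labels `"H"`/`"L"` with attributes `threshold` (the
#'   sample mean) and `summary` (a tibble with per-group n, mean and sd).
#' @export
#' @examples
#' mean_split(c(1, 2, 3, 4))  # H for 3 and 4
mean_split <- function(values) {
  if (length(values) < 2L || !is.numeric(values)) {
    gbm_abort("`values` must be a numeric vector with at least 2 entries.",
              "gbm_validation")
  }
  m <- mean(values)
  labels <- factor(ifelse(values > m, "H", "L"), levels = c("H", "L"))
  summary <- tibble::tibble(group = factor(c("H", "L"), levels = c("H", "L"))) |>
    dplyr::mutate(
      n = as.integer(table(labels)[as.character(.data$group)]),
      mean = vapply(as.character(.data$group),
                    function(g) mean(values[labels == g]), numeric(1)),
      sd = vapply(as.character(.data$group),
                  function(g) stats::sd(values[labels == g]), numeric(1))
    )
  structure(labels, threshold = m, summary = summary)
}

#' Add High/Low intake groups to an intake table
#'
#' Applies [mean_split()] to the protein and lipid columns of an intake table.
#'
#' @param intake A tibble from [compute_monthly_intake()].
#' @return `intake` with added factor columns `protein_group`, `lipid_group`.
#' @export
add_intake_groups <- function(intake) {
  intake |>
    dplyr::mutate(
      protein_group = factor(as.character(mean_split(.data$protein_g_month)),
                             levels = c("H", "L")),
      lipid_group = factor(as.character(mean_split(.data$lipid_g_month)),
                           levels = c("H", "L"))
    )
}

#' Welch's unequal-variance t test from group summaries
#'
#' Computes Welch's t statistic, the Welch-Satterthwaite degrees of freedom
#' and the two-sided p value from per-group sample sizes, means and standard
#' deviations, so published summary statistics can be re-analysed directly.
#'
#' @param n1,mean1,sd1 Size, mean and SD of the first group.
#' @param n2,mean2,sd2 Size, mean and SD of the second group.
#' @return A tibble with columns `statistic`, `df`, `p.value`,
#'   `estimate` (mean1 - mean2).
#' @export
#' @examples
#' welch_t_summary(9, 278.22, 74.80, 22, 185.41, 60.28)
welch_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) {
    gbm_abort("Each group needs at least 2 observations.", "gbm_validation")
  }
  if (sd1 <= 0 || sd2 <= 0) {
    gbm_abort("Group standard deviations must be positive.", "gbm_validation")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(
    statistic = t,
    df = df,
    p.value = 2 * stats::pt(-abs(t), df),
    estimate = mean1 - mean2
  )
}

#' Welch's t test on raw samples
#'
#' Summarises each sample then delegates to [welch_t_summary()].
#'
#' @param x,y Numeric vectors, one per group.
#' @inherit welch_t_summary return
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    gbm_abort("Each group needs at least 2 observations.", "gbm_validation")
  }
  welch_t_summary(length(x), mean(x), stats::sd(x),
                  length(y), mean(y), stats::sd(y))
}

#' Percent of individuals shared between two intake groups
#'
#' The overlap of two groups as a percentage of their union:
#' `100 * n_both / (n_a + n_b - n_both)`, reported to one decimal
#' (round-half-even).
#'
#' @param n_a,n_b Sizes of the two groups.
#' @param n_both Number of individuals in both groups.
#' @return A tibble with columns `n_a`, `n_b`, `n_both`, `n_union`,
#'   `percent_shared` (one decimal).
#' @export
#' @examples
#' group_overlap(11, 9, 6)   # 42.9% of the union shared
group_overlap <- function(n_a, n_b, n_both) {
  if (n_both > min(n_a, n_b)) {
    gbm_abort("`n_both` cannot exceed the smaller group size.",
              "gbm_validation")
  }
  n_union <- n_a + n_b - n_both
  tibble::tibble(
    n_a = n_a, n_b = n_b, n_both = n_both, n_union = n_union,
    percent_shared = round(100 * n_both / n_union, 1)
  )
}

#' Compare a variable between two groups
#'
#' Mann-Whitney U (Wilcoxon rank-sum, ties midranked; the smaller of the two
#' U orientations is reported) or Welch's t test on raw values.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector aligned with `values`.
#' @param method `"mann_whitney_u"` (default) or `"welch_t"`.
#' @return A tibble with columns `method`, `statistic`, `p.value`, `n1`, `n2`.
#' @export
group_compare <- function(values, labels,
                          method = c("mann_whitney_u", "welch_t")) {
  method <- match.arg(method)
  labels <- factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    gbm_abort("`labels` must define two nonempty groups.", "gbm_validation")
  }
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (method == "welch_t") {
    res <- welch_t(g1, g2)
    return(tibble::tibble(method = method, statistic = res$statistic,
                          p.value = res$p.value,
                          n1 = length(g1), n2 = length(g2)))
  }
  wt <- stats::wilcox.test(g1, g2, exact = NULL)
  u1 <- unname(wt$statistic)
  u <- min(u1, length(g1) * length(g2) - u1)
  tibble::tibble(method = method, statistic = u, p.value = wt$p.value,
                 n1 = length(g1), n2 = length(g2))
}
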