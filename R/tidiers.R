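#' Tidy an MST result into its edge list
#'
#' @param x An `mst_result`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @exportS3Method generics::tidy
tidy.mst_result <- function(x, ...) {
  x$edges
}

#' One-row summary of an MST result
#'
#' @param x An `mst_result`.
#' @param ... Unused.
#' @return A tibble with `node_count`, `n_edges`, `total_weight`.
#' @exportS3Method generics::glance
glance.mst_result <- function(x, ...) {
  tibble::tibble(node_count = x$node_count, n_edges = nrow(x$edges),
                 total_weight = x$total_weight)
}

#' Tidy an MI matrix into ROI-pair rows
#'
#' @param x An `mi_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `roi1`, `roi2`, `mi`, `band`, `condition`,
#'   `group`.
#' @exportS3Method generics::tidy
tidy.mi_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    roi1 = rownames(x$values)[idx[, 1]],
    roi2 = colnames(x$values)[idx[, 2]],
    mi = x$values[idx],
    band = x$band, condition = x$condition, group = x$group
  )
}

#' Tidy a random-split null distribution
#'
#' @param x A `random_split_null`.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `difference`.
#' @exportS3Method generics::tidy
tidy.random_split_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null), difference = x$null)
}

#' One-row summary of a random-split null
#'
#' @param x A `random_split_null`.
#' @param ... Unused.
#' @return A tibble with `observed`, `p_value`, `k`, `n`, `m`.
#' @exportS3Method generics::glance
glance.random_split_null <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value,
                 k = x$k, n = x$n, m = x$m)
}
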