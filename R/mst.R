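#' Build a weighted undirected network from a symmetric matrix
#'
#' The matrix entries become edge weights of the complete graph on the node
#' labels; the diagonal is dropped. Mutual-information matrices and
#' co-occurrence weight matrices both enter the spanning-tree analysis this
#' way.
#'
#' @param matrix Symmetric numeric matrix (asymmetry beyond 1e-9 is an error).
#' @param node_labels Node names; defaults to the matrix rownames.
#' @param metadata Named list attached to the network (e.g. band, condition,
#'   group, source).
#' @param drop_zero_edges If `TRUE`, weight-0 entries are treated as absent
#'   edges rather than edges of weight zero (used for co-occurrence counts).
#' @return A `weighted_network`: list with `nodes`, `edges` (tibble `from`,
#'   `to`, `weight`) and `metadata`.
#' @export
build_network <- function(matrix, node_labels = rownames(matrix),
                          metadata = list(), drop_zero_edges = FALSE) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    gbm_abort("`matrix` must be square.", "gbm_validation")
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1, , drop = TRUE]
    gbm_abort(sprintf("Non-finite weight at [%d, %d].", bad[1], bad[2]),
              "gbm_validation")
  }
  if (max(abs(matrix - t(matrix))) > 1e-9) {
    gbm_abort("`matrix` is not symmetric (tolerance 1e-9).", "gbm_validation")
  }
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(nrow(matrix)))
  n <- length(node_labels)
  idx <- which(upper.tri(matrix), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = node_labels[idx[, 1]],
    to = node_labels[idx[, 2]],
    weight = matrix[idx]
  )
  if (drop_zero_edges) edges <- edges[edges$weight != 0, , drop = FALSE]
  structure(list(nodes = node_labels, edges = edges, metadata = metadata),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# connected components by repeated neighbour expansion
network_components <- function(network) {
  nodes <- network$nodes
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (i in seq_len(nrow(network$edges))) {
    a <- comp[[network$edges$from[i]]]
    b <- comp[[network$edges$to[i]]]
    if (a != b) comp[comp == b] <- a
  }
  split(nodes, comp)
}

#' Minimum spanning tree of a weighted network
#'
#' Kruskal's algorithm with deterministic tie-breaking (edges sorted by
#' weight, then lexicographically by node pair). Negative weights are valid
#' and sort first. The tree's total weight is the connectivity statistic
#' used throughout the package.
#'
#' @param network A `weighted_network` from [build_network()].
#' @return An `mst_result`: list with `edges` (tibble `from`, `to`,
#'   `weight`), `total_weight` and `node_count`.
#' @export
#' @examples
#' m <- matrix(1, 4, 4); diag(m) <- 0
#' rownames(m) <- colnames(m) <- LETTERS[1:4]
#' minimum_spanning_tree(build_network(m))$total_weight  # 3
minimum_spanning_tree <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  if (n < 2L) gbm_abort("Need at least 2 nodes.", "gbm_validation")
  comps <- network_components(network)
  if (length(comps) > 1L) {
    gbm_abort(paste0("Network is disconnected; components: ",
                     paste(vapply(comps, function(cc)
                       paste(cc, collapse = ","), character(1)),
                       collapse = " | ")),
              "gbm_disconnected")
  }
  edges <- network$edges
  ord <- order(edges$weight, edges$from, edges$to, method = "radix")
  edges <- edges[ord, , drop = FALSE]

  parent <- stats::setNames(seq_len(n), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  keep <- logical(nrow(edges))
  taken <- 0L
  for (i in seq_len(nrow(edges))) {
    ra <- find(match(edges$from[i], nodes))
    rb <- find(match(edges$to[i], nodes))
    if (ra != rb) {
      parent[[rb]] <- ra
      keep[i] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  tree <- edges[keep, , drop = FALSE]
  structure(list(edges = tree,
                 total_weight = sum(tree$weight),
                 node_count = n,
                 metadata = network$metadata),
            class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf("<mst_result: %d nodes, total weight %.4g>\n",
              x$node_count, x$total_weight))
  invisible(x)
}

#' Percent difference between group MST weights
#'
#' `100 * (w_high - w_low) / w_high`: the high-intake group's tree weight is
#' the baseline, so a positive value means connectivity is lower in the
#' low-intake group.
#'
#' @param w_high,w_low Total MST weights of the high- and low-intake groups.
#' @return Percent difference (signed scalar).
#' @export
#' @examples
#' mst_percent_difference(2, 1)  # 50
mst_percent_difference <- function(w_high, w_low) {
  if (w_high == 0) {
    gbm_abort("Percent difference undefined: `w_high` is 0.",
              "gbm_undefined_result")
  }
  100 * (w_high - w_low) / w_high
}

#' Random-subnetwork null model for a group-difference statistic
#'
#' Repeatedly splits the cohort at random into subgroups of sizes `n` and
#' `m` (without replacement within each replicate), recomputes the network
#' statistic on each subgroup's data, and records the difference
#' `statistic_fn(n-set) - statistic_fn(m-set)`. The observed difference is
#' located in this null with the add-one empirical p value
#' `(r + 1) / (k + 1)`, one-sided (null >= observed).
#'
#' @param data A data frame of per-subject observations.
#' @param n,m Subgroup sizes (`n + m` at most the number of subjects).
#' @param k Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param statistic_fn Function: data subset -> scalar statistic (typically
#'   data -> MI network -> MST total weight).
#' @param observed Observed difference to locate in the null; defaults to the
#'   statistic on the first `n` vs remaining subjects in `data`'s own order.
#' @param id_col Name of the subject-id column (default `"subject_id"`).
#' @return A `random_split_null`: list with `null` (length-`k` numeric),
#'   `observed`, `p_value`, `n`, `m`, `k`.
#' @export
random_split_null <- function(data, n, m, k = 1000, seed = 1,
                              statistic_fn, observed = NULL,
                              id_col = "subject_id") {
  subjects <- unique(data[[id_col]])
  if (k < 100) gbm_abort("`k` must be at least 100.", "gbm_validation")
  if (n + m > length(subjects)) {
    gbm_abort(sprintf("n + m = %d exceeds the %d available subjects.",
                      n + m, length(subjects)),
              "gbm_validation")
  }
  stat_for <- function(ids) statistic_fn(data[data[[id_col]] %in% ids, , drop = FALSE])
  if (is.null(observed)) {
    observed <- stat_for(subjects[seq_len(n)]) -
      stat_for(subjects[seq(n + 1L, n + m)])
  }
  null <- with_seed(seed, {
    vapply(seq_len(k), function(i) {
      pick <- sample(subjects, n + m)
      stat_for(pick[seq_len(n)]) - stat_for(pick[seq(n + 1L, n + m)])
    }, numeric(1))
  })
  r <- sum(null >= observed)
  structure(list(null = null, observed = observed,
                 p_value = (r + 1) / (k + 1), n = n, m = m, k = k),
            class = "random_split_null")
}

#' @export
print.random_split_null <- function(x, ...) {
  cat(sprintf(
    "<random_split_null: k = %d splits of %d vs %d; observed diff %.4g, p = %.4g>\n",
    x$k, x$n, x$m, x$observed, x$p_value))
  invisible(x)
}
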