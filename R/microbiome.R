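#' Rarefy an ASV count table to fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via `vegan::rrarefy`, seeded). Samples shallower than `depth` are
#' dropped with a warning.
#'
#' @param counts Samples x ASVs integer matrix (rownames = sample ids).
#' @param depth Target depth (default 21000 reads).
#' @param seed Integer seed.
#' @return Rarefied matrix with attribute `dropped` (ids of removed
#'   samples).
#' @export
rarefy_counts <- function(counts, depth = 21000, seed = 1) {
  if (depth <= 0) gbm_abort("`depth` must be positive.", "gbm_validation")
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  shallow <- totals < depth
  if (any(shallow)) {
    warning(sprintf("Dropping %d sample(s) below depth %d: %s",
                    sum(shallow), depth,
                    paste(rownames(counts)[shallow], collapse = ", ")),
            call. = FALSE)
    counts <- counts[!shallow, , drop = FALSE]
  }
  if (nrow(counts) == 0L) {
    gbm_abort("No samples reach the rarefaction depth.", "gbm_empty_result")
  }
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      # vegan flags any table whose smallest count exceeds 1 as suspicious;
      # rarefied/filtered tables do this routinely
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  structure(out, dropped = rownames(counts)[shallow])
}

#' Per-sample alpha diversity
#'
#' Shannon's index in nats (`-sum(p_i * log(p_i))` over nonzero
#' proportions) and the number of observed ASVs, on a rarefied table.
#'
#' @param counts Samples x ASVs matrix (typically rarefied).
#' @return A tibble with columns `sample_id`, `shannon`, `observed`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0)) {
    gbm_abort("All-zero sample(s) present.", "gbm_validation")
  }
  tibble::tibble(
    sample_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    shannon = as.numeric(vegan::diversity(counts, index = "shannon")),
    observed = as.integer(rowSums(counts > 0))
  )
}

#' Welch tests of alpha diversity between intake groups
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param groups Two-level grouping vector aligned with `alpha`'s rows.
#' @return A tibble with one row per index: `index`, `statistic`, `df`,
#'   `p.value`.
#' @export
alpha_group_test <- function(alpha, groups) {
  groups <- factor(groups)
  purrr::map_dfr(c("shannon", "observed"), function(idx) {
    v <- alpha[[idx]]
    g1 <- v[groups == levels(groups)[1]]
    g2 <- v[groups == levels(groups)[2]]
    if (stats::sd(g1) == 0 || stats::sd(g2) == 0) {
      warning(sprintf("`%s` has zero variance in a group; test undefined.",
                      idx), call. = FALSE)
      return(tibble::tibble(index = idx, statistic = NA_real_,
                            df = NA_real_, p.value = NA_real_))
    }
    res <- welch_t(g1, g2)
    tibble::tibble(index = idx, statistic = res$statistic, df = res$df,
                   p.value = res$p.value)
  })
}

#' Random-forest Gini importance screening of ASVs
#'
#' Fits a random forest classifying samples into High vs Low intake and
#' reports each ASV's Mean Decrease Gini importance, plus the number of
#' ASVs with strictly positive importance (the "informative" count).
#' Samples and ASVs are put into a fixed canonical (lexicographic) order
#' before any seeded randomness so results are reproducible.
#'
#' @param counts Samples x ASVs matrix.
#' @param labels Two-level grouping vector aligned with the rows of
#'   `counts`.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @param ... Passed to [randomForest::randomForest()] (e.g. `mtry`,
#'   `replace`, `sampsize`).
#' @return A list with `importance` (tibble: `asv_id`,
#'   `mean_decrease_gini`, sorted decreasing) and `n_informative`.
#' @export
gini_importance <- function(counts, labels, n_trees = 500, seed = 1, ...) {
  counts <- as.matrix(counts)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    gbm_abort("`labels` must contain two classes.", "gbm_validation")
  }
  if (nrow(counts) < 4L) gbm_abort("Need at least 4 samples.",
                                   "gbm_validation")
  ord_s <- order(rownames(counts) %||% seq_len(nrow(counts)))
  ord_a <- order(colnames(counts) %||% seq_len(ncol(counts)))
  x <- counts[ord_s, ord_a, drop = FALSE]
  y <- labels[ord_s]
  fit <- with_seed(seed,
                   randomForest::randomForest(x = as.data.frame(x), y = y,
                                              ntree = n_trees, ...))
  gini <- randomForest::importance(fit)[, "MeanDecreaseGini"]
  imp <- tibble::tibble(asv_id = names(gini),
                        mean_decrease_gini = as.numeric(gini)) |>
    dplyr::arrange(dplyr::desc(.data$mean_decrease_gini))
  list(importance = imp, n_informative = sum(imp$mean_decrease_gini > 0))
}

#' Probabilistic co-occurrence weights for one group's ASV table
#'
#' Presence is `count >= presence_threshold`. For each pair of ASVs present
#' in the group, the number of samples where both occur is referred to its
#' hypergeometric distribution given the two incidences: with `N` samples
#' and incidences `N1`, `N2`, `P(j) = C(N1, j) C(N - N1, N2 - j) / C(N,
#' N2)`. `p_gt` is `P(J >= observed)` and `p_lt` is `P(J <= observed)`. The
#' edge weight is the observed co-occurrence count (or `observed -
#' expected` with `weight_type = "obs_minus_exp"`); the weight matrix feeds
#' the group's network and MST.
#'
#' @param counts Samples x ASVs matrix for the samples of one intake group.
#' @param presence_threshold Minimum count that counts as presence
#'   (default 1).
#' @param weight_type `"observed"` (default) or `"obs_minus_exp"`.
#' @return A list with `pairs` (tibble: `asv1`, `asv2`, `n_sites`,
#'   `incidence_1`, `incidence_2`, `observed`, `expected`, `p_lt`, `p_gt`,
#'   `weight`) and `weights` (symmetric matrix over the group's present
#'   ASVs).
#' @export
cooccur_weights <- function(counts, presence_threshold = 1,
                            weight_type = c("observed", "obs_minus_exp")) {
  weight_type <- match.arg(weight_type)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) {
    gbm_abort("Need at least 2 samples in the group.", "gbm_validation")
  }
  pres <- counts >= presence_threshold
  keep <- colSums(pres) > 0
  pres <- pres[, keep, drop = FALSE]
  asvs <- colnames(pres) %||% as.character(which(keep))
  n_sites <- nrow(pres)
  inc <- colSums(pres)
  co <- crossprod(pres)  # observed co-occurrence counts
  idx <- which(upper.tri(co), arr.ind = TRUE)
  i1 <- idx[, 1]; i2 <- idx[, 2]
  obs <- co[idx]
  expected <- inc[i1] * inc[i2] / n_sites
  p_gt <- stats::phyper(obs - 1, inc[i1], n_sites - inc[i1], inc[i2],
                        lower.tail = FALSE)
  p_lt <- stats::phyper(obs, inc[i1], n_sites - inc[i1], inc[i2])
  weight <- if (weight_type == "observed") obs else obs - expected
  pairs <- tibble::tibble(
    asv1 = asvs[i1], asv2 = asvs[i2], n_sites = n_sites,
    incidence_1 = as.integer(inc[i1]), incidence_2 = as.integer(inc[i2]),
    observed = as.integer(obs), expected = as.numeric(expected),
    p_lt = as.numeric(p_lt), p_gt = as.numeric(p_gt),
    weight = as.numeric(weight)
  )
  weights <- matrix(0, length(asvs), length(asvs),
                    dimnames = list(asvs, asvs))
  weights[cbind(i1, i2)] <- weight
  weights[cbind(i2, i1)] <- weight
  list(pairs = pairs, weights = weights)
}

#' Group MSTs and percent difference for the gut-microbiota network
#'
#' Builds each group's co-occurrence network (zero-weight pairs are absent
#' edges), restricts to the largest connected component when necessary
#' (with a message), computes both minimum spanning trees and the percent
#' difference of their total weights with the high group as baseline.
#'
#' @param weights_high,weights_low Co-occurrence weight matrices from
#'   [cooccur_weights()] for the High and Low groups.
#' @return A list with `mst_high`, `mst_low` (both [minimum_spanning_tree()]
#'   results) and `percent_difference`.
#' @export
gm_mst <- function(weights_high, weights_low) {
  one <- function(w, group) {
    if (nrow(w) < 2L) {
      gbm_abort("Fewer than 2 ASVs present in a group.", "gbm_validation")
    }
    net <- build_network(w, metadata = list(source = "cooccur", group = group),
                         drop_zero_edges = TRUE)
    comps <- network_components(net)
    if (length(comps) > 1L) {
      main <- comps[[which.max(lengths(comps))]]
      message(sprintf(
        "Group %s co-occurrence network is disconnected; keeping largest component (%d of %d ASVs).",
        group, length(main), length(net$nodes)))
      keep <- net$edges$from %in% main & net$edges$to %in% main
      net <- structure(list(nodes = main,
                            edges = net$edges[keep, , drop = FALSE],
                            metadata = net$metadata),
                       class = "weighted_network")
    }
    minimum_spanning_tree(net)
  }
  mst_high <- one(weights_high, "H")
  mst_low <- one(weights_low, "L")
  list(mst_high = mst_high, mst_low = mst_low,
       percent_difference = mst_percent_difference(mst_high$total_weight,
                                                   mst_low$total_weight))
}
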