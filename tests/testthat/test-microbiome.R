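test_that("rarefaction conserves depth and expectation", {
  set.seed(51)
  counts <- matrix(rpois(60, 40), nrow = 4,
                   dimnames = list(paste0("s", 1:4), paste0("a", 1:15)))

  # a sample already at the target depth is returned unchanged
  target <- sum(counts[1, ])
  one <- rarefy_counts(counts[1, , drop = FALSE], depth = target, seed = 1)
  expect_equal(unclass(one)[1, ], counts[1, ], ignore_attr = TRUE)

  out <- rarefy_counts(counts, depth = 300, seed = 2)
  expect_true(all(rowSums(out) == 300))

  # expected rarefied count is the ASV's fraction times the depth
  f <- counts[1, 1] / sum(counts[1, ])
  draws <- vapply(1:100, function(s) {
    rarefy_counts(counts[1, , drop = FALSE], depth = 300, seed = s)[1, 1]
  }, numeric(1))
  se <- sqrt(300 * f * (1 - f)) / sqrt(100)
  expect_lt(abs(mean(draws) - f * 300), 5 * se)

  shallow <- counts; shallow[2, ] <- 0L; shallow[2, 1] <- 10L
  expect_warning(rarefy_counts(shallow, depth = 300, seed = 1),
                 regexp = "s2")
  expect_error(rarefy_counts(counts, depth = 0, seed = 1),
               class = "gbm_validation")
})

test_that("alpha diversity matches closed forms and a direct recomputation", {
  uniform <- matrix(5L, nrow = 1, ncol = 8,
                    dimnames = list("s1", paste0("a", 1:8)))
  a <- alpha_diversity(uniform)
  expect_equal(a$shannon, log(8))
  expect_equal(a$observed, 8L)

  single <- matrix(c(42L, 0L, 0L), nrow = 1,
                   dimnames = list("s1", paste0("a", 1:3)))
  s <- alpha_diversity(single)
  expect_equal(s$shannon, 0)
  expect_equal(s$observed, 1L)

  set.seed(52)
  counts <- matrix(rpois(80, 1), nrow = 4,
                   dimnames = list(paste0("s", 1:4), paste0("a", 1:20)))
  counts[, 1] <- counts[, 1] + 1L  # no all-zero sample
  ours <- alpha_diversity(counts)
  manual <- apply(counts, 1, function(r) {
    p <- r[r > 0] / sum(r)
    -sum(p * log(p))
  })
  expect_equal(ours$shannon, unname(manual), tolerance = 1e-12)

  zero <- counts; zero[1, ] <- 0L
  expect_error(alpha_diversity(zero), class = "gbm_validation")

  groups <- c("H", "H", "L", "L")
  tests <- alpha_group_test(ours, groups)
  expect_equal(tests$index, c("shannon", "observed"))
  expect_true(all(tests$p.value >= 0 & tests$p.value <= 1))
})

test_that("Gini importance finds a planted discriminating ASV", {
  make_table <- function(seed) {
    withr::with_seed(seed, {
      n <- 24
      counts <- matrix(rpois(n * 20, 20), nrow = n,
                       dimnames = list(sprintf("s%02d", 1:n),
                                       sprintf("a%02d", 1:20)))
      labels <- rep(c("H", "L"), each = n / 2)
      counts[, 1] <- ifelse(labels == "H", rpois(n, 60), rpois(n, 5))
      list(counts = counts, labels = labels)
    })
  }
  hits <- vapply(1:10, function(seed) {
    d <- make_table(seed)
    res <- gini_importance(d$counts, d$labels, n_trees = 100, seed = seed)
    res$importance$asv_id[1] == "a01"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # permuted labels: the planted ASV's importance collapses into the bulk
  d <- make_table(99)
  perm <- withr::with_seed(7, sample(d$labels))
  res_perm <- gini_importance(d$counts, perm, n_trees = 100, seed = 1)
  res_real <- gini_importance(d$counts, d$labels, n_trees = 100, seed = 1)
  top_share <- function(r) max(r$importance$mean_decrease_gini) /
    sum(r$importance$mean_decrease_gini)
  expect_gt(top_share(res_real), 2 * top_share(res_perm))

  expect_error(gini_importance(d$counts, rep("H", nrow(d$counts))),
               class = "gbm_validation")
})

test_that("a single tree's Gini importance matches the hand computation", {
  # 4 samples, feature a1 separates the classes perfectly, a2 is constant:
  # root Gini 0.5 with 4 samples, pure children -> decrease 4*0.5 - 0 = 2
  counts <- matrix(c(0, 0, 10, 10,
                     3, 3, 3, 3), ncol = 2,
                   dimnames = list(paste0("s", 1:4), c("a1", "a2")))
  labels <- c("H", "H", "L", "L")
  res <- gini_importance(counts, labels, n_trees = 1, seed = 1,
                         mtry = 2, replace = FALSE,
                         sampsize = 4, nodesize = 1)
  imp <- res$importance
  expect_equal(imp$mean_decrease_gini[imp$asv_id == "a1"], 2)
  expect_equal(imp$mean_decrease_gini[imp$asv_id == "a2"], 0)
  expect_equal(res$n_informative, 1)
})

test_that("co-occurrence probabilities follow the hypergeometric model", {
  # N = 4 samples, both incidences 2: P(j) = (1/6, 2/3, 1/6)
  pres <- matrix(c(1, 1, 0, 0,
                   0, 1, 1, 0), ncol = 2,
                 dimnames = list(paste0("s", 1:4), c("a1", "a2")))
  cw <- cooccur_weights(pres)
  p <- cw$pairs
  expect_equal(p$observed, 1L)
  expect_equal(p$expected, 2 * 2 / 4)
  expect_equal(p$p_lt, 1 / 6 + 2 / 3)
  expect_equal(p$p_gt, 2 / 3 + 1 / 6)

  # ubiquitous pair: observed = expected = N and P(J = N) = 1
  all_pres <- matrix(1, nrow = 5, ncol = 2,
                     dimnames = list(paste0("s", 1:5), c("a1", "a2")))
  cw2 <- cooccur_weights(all_pres)
  expect_equal(cw2$pairs$observed, 5L)
  expect_equal(cw2$pairs$expected, 5)
  expect_equal(cw2$pairs$p_gt, 1)
  expect_equal(cw2$pairs$p_lt, 1)

  # disjoint incidences: observed 0 and p_lt = P(0)
  disj <- matrix(c(1, 1, 0, 0, 0,
                   0, 0, 1, 1, 0), ncol = 2,
                 dimnames = list(paste0("s", 1:5), c("a1", "a2")))
  cw3 <- cooccur_weights(disj)
  expect_equal(cw3$pairs$observed, 0L)
  expect_equal(cw3$pairs$p_lt,
               stats::dhyper(0, 2, 3, 2))

  expect_error(cooccur_weights(pres[1, , drop = FALSE]),
               class = "gbm_validation")
})

test_that("gm_mst compares group networks with the high group as baseline", {
  cfg <- test_config(seed = 61)
  tab <- generate_asv_table(cfg)
  cw <- cooccur_weights(tab$counts[tab$metadata$group == "H", ])

  res <- suppressMessages(gm_mst(cw$weights, cw$weights))
  expect_equal(res$percent_difference, 0)

  pair <- matrix(c(0, 3, 3, 0), 2, 2,
                 dimnames = list(c("a1", "a2"), c("a1", "a2")))
  res2 <- gm_mst(pair, pair)
  expect_equal(res2$mst_high$total_weight, 3)

  # planted association in the high group yields the heavier tree even
  # though the high group has fewer samples (study-like 11 vs 20 split)
  hits <- vapply(1:10, function(seed) {
    cfg <- test_config(seed = 700 + seed, n_samples = 31,
                       n_samples_high = 11, n_asvs = 40)
    tab <- generate_asv_table(cfg)
    rare <- suppressWarnings(rarefy_counts(tab$counts, cfg$min_depth,
                                           seed = seed))
    g <- tab$metadata$group[match(rownames(rare), tab$metadata$sample_id)]
    gm <- suppressMessages(gm_mst(
      cooccur_weights(rare[g == "H", , drop = FALSE])$weights,
      cooccur_weights(rare[g == "L", , drop = FALSE])$weights))
    gm$mst_high$total_weight > gm$mst_low$total_weight
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
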