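test_that("build_network enumerates unordered pairs and validates weights", {
  m <- random_weight_matrix(5)
  net <- build_network(m)
  expect_s3_class(net, "weighted_network")
  expect_equal(nrow(net$edges), 10)  # C(5, 2)

  m2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  net2 <- build_network(m2)
  expect_equal(net2$edges$weight, 2)

  bad <- m; bad[1, 2] <- NaN
  expect_error(build_network(bad), class = "gbm_validation", regexp = "\\[1, 2\\]")
  asym <- m; asym[1, 2] <- asym[1, 2] + 1e-6
  expect_error(build_network(asym), class = "gbm_validation")
})

test_that("Kruskal MST matches closed forms and the exhaustive oracle", {
  # uniform complete graph: (n-1) * w
  m <- random_weight_matrix(4, rep(1, 6))
  expect_equal(minimum_spanning_tree(build_network(m))$total_weight, 3)

  # K4 with weights AB:1 AC:2 AD:3 BC:4 BD:5 CD:6 -> star at A, total 6
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- 1; m["A", "C"] <- 2; m["A", "D"] <- 3
  m["B", "C"] <- 4; m["B", "D"] <- 5; m["C", "D"] <- 6
  m <- m + t(m)
  net <- build_network(m)
  res <- minimum_spanning_tree(net)
  expect_equal(res$total_weight, 6)
  expect_setequal(paste(res$edges$from, res$edges$to),
                  c("A B", "A C", "A D"))
  expect_equal(brute_force_mst(net$nodes, net$edges), 6)

  # a path graph is its own MST
  path <- tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "D"),
                         weight = c(1, 5, 2))
  pnet <- structure(list(nodes = LETTERS[1:4], edges = path,
                         metadata = list()), class = "weighted_network")
  pres <- minimum_spanning_tree(pnet)
  expect_equal(pres$total_weight, 8)
  expect_equal(nrow(pres$edges), 3)
})

test_that("MST handles negative weights and reports disconnection", {
  m <- random_weight_matrix(5, c(-1, -2, 0.5, 1, 2, -0.3, 0.1, 0.4, 3, -5))
  net <- build_network(m)
  res <- minimum_spanning_tree(net)
  expect_equal(res$total_weight, brute_force_mst(net$nodes, net$edges))

  disc <- structure(list(
    nodes = c("A", "B", "C", "D"),
    edges = tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                           weight = c(1, 1)),
    metadata = list()), class = "weighted_network")
  expect_error(minimum_spanning_tree(disc), class = "gbm_disconnected",
               regexp = "A,B")
})

test_that("MST weight is invariant to relabeling and shifts by (n-1)c", {
  set.seed(3)
  m <- random_weight_matrix(6)
  w0 <- minimum_spanning_tree(build_network(m))$total_weight

  perm <- sample(6)
  mp <- m[perm, perm]
  expect_equal(minimum_spanning_tree(build_network(mp))$total_weight, w0)

  shift <- m + 2.5; diag(shift) <- 0
  expect_equal(minimum_spanning_tree(build_network(shift))$total_weight,
               w0 + 5 * 2.5)
})

test_that("Kruskal agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(9)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    m <- random_weight_matrix(n, stats::rnorm(n * (n - 1) / 2))
    ours <- minimum_spanning_tree(build_network(m))$total_weight
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ref <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("percent difference keeps its sign convention", {
  expect_equal(mst_percent_difference(2, 2), 0)
  expect_equal(mst_percent_difference(2, 1), 50)
  expect_equal(mst_percent_difference(1, 2), -100)
  expect_error(mst_percent_difference(0, 1), class = "gbm_undefined_result")
})

test_that("random-split null is seeded, degenerate-safe and validated", {
  df <- tibble::tibble(subject_id = sprintf("S%02d", 1:12), v = rnorm(12))

  const <- random_split_null(df, n = 4, m = 6, k = 100, seed = 5,
                             statistic_fn = function(d) 1)
  expect_true(all(const$null == 0))
  expect_equal(const$p_value, 1)

  f <- function(d) mean(d$v)
  a <- random_split_null(df, n = 4, m = 6, k = 120, seed = 9, statistic_fn = f)
  b <- random_split_null(df, n = 4, m = 6, k = 120, seed = 9, statistic_fn = f)
  expect_identical(a$null, b$null)

  expect_error(random_split_null(df, n = 7, m = 6, k = 100, seed = 1,
                                 statistic_fn = f),
               class = "gbm_validation")
  expect_error(random_split_null(df, n = 3, m = 4, k = 10, seed = 1,
                                 statistic_fn = f),
               class = "gbm_validation")
})

test_that("expected MST weight grows with node count for i.i.d. weights", {
  set.seed(13)
  mean_w <- vapply(c(5, 10, 20), function(n) {
    mean(replicate(60, {
      m <- random_weight_matrix(n, stats::runif(n * (n - 1) / 2))
      minimum_spanning_tree(build_network(m))$total_weight
    }))
  }, numeric(1))
  expect_true(all(diff(mean_w) > 0))
})
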