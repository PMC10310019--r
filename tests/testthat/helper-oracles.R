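# Independent oracles and small fixtures used across the suite.

# Exhaustive minimum spanning tree: try every (n-1)-edge subset of the edge
# list, keep those that span and are connected, return the minimum total.
brute_force_mst <- function(nodes, edges) {
  n <- length(nodes)
  best <- Inf
  subsets <- utils::combn(nrow(edges), n - 1)
  for (j in seq_len(ncol(subsets))) {
    sub <- edges[subsets[, j], , drop = FALSE]
    if (!setequal(unique(c(sub$from, sub$to)), nodes)) next
    # connectivity by label propagation
    comp <- stats::setNames(seq_along(nodes), nodes)
    for (i in seq_len(nrow(sub))) {
      a <- comp[[sub$from[i]]]; b <- comp[[sub$to[i]]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1L) best <- min(best, sum(sub$weight))
  }
  best
}

# Mann-Whitney U by direct enumeration of pairwise wins (ties count 1/2).
brute_force_u <- function(x, y) {
  u_x <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(u_x, length(x) * length(y) - u_x)
}

# random symmetric weight matrix with labelled nodes
random_weight_matrix <- function(n, weights = stats::runif(n * (n - 1) / 2)) {
  m <- matrix(0, n, n, dimnames = list(LETTERS[seq_len(n)],
                                       LETTERS[seq_len(n)]))
  m[upper.tri(m)] <- weights
  m + t(m)
}

# a small synthetic cohort config sized for unit tests; any field can be
# overridden through ...
test_config <- function(seed = 1, ...) {
  defaults <- list(
    n_subjects_per_group = c(high = 6, low = 7),
    seed = seed, fs = 128, duration = 12,
    n_samples = 13, n_samples_high = 6, n_asvs = 30,
    depth = 1200, min_depth = 1000)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# 19-channel recording filled by a generator function of (channel, n)
make_recording <- function(n_samples, fs = 128, fill = function(ch, n) stats::rnorm(n),
                           condition = "open_eyes", subject_id = "S01") {
  ch <- gutbrainmst::montage_1020()
  data <- t(vapply(seq_along(ch), function(i) fill(i, n_samples),
                   numeric(n_samples)))
  gutbrainmst::eeg_recording(data, fs = fs, channels = ch,
                             subject_id = subject_id, condition = condition)
}
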