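#' Generate a synthetic ASV count table with planted co-occurrence
#'
#' Presence-absence structure is planted per intake group through a latent
#' per-sample community state: within each group exactly half of the samples
#' carry the state (a random subset), and each ASV's presence copies its
#' sample's state with probability equal to the group's co-occurrence
#' strength (otherwise it is an independent Bernoulli(1/2)). At strength 1 every tracking pair is fully linked (the
#' observed co-occurrence equals the smaller incidence); at strength 0 all
#' pairs are independent. Counts for present ASVs are multinomial over
#' log-normal relative abundances with exactly `depth` reads per sample, so
#' every sample supports rarefaction to `min_depth`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `counts` (samples x ASVs integer matrix) and
#'   `metadata` (tibble: `sample_id`, `group`).
#' @export
generate_asv_table <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_samples
  n_high <- config$n_samples_high
  p <- config$n_asvs
  groups <- rep(c("H", "L"), c(n_high, n - n_high))
  ids <- sprintf("S%02d", seq_len(n))
  asvs <- sprintf("ASV_%03d", seq_len(p))

  with_seed(config$seed + 1L, {
    presence <- matrix(0L, n, p, dimnames = list(ids, asvs))
    for (g in c("H", "L")) {
      rows <- which(groups == g)
      s <- if (g == "H") config$cooccur_strength_high else config$cooccur_strength_low
      # the latent community state is carried by exactly half of the group's
      # samples, so the planted co-occurrence level does not fluctuate with a
      # Binomial draw of state-carrying samples
      on <- sample(rows, round(length(rows) / 2))
      for (i in rows) {
        latent <- as.integer(i %in% on)
        track <- stats::runif(p) < s
        presence[i, ] <- ifelse(track, latent, stats::rbinom(p, 1, 0.5))
      }
    }
    # no empty samples: force the first ASV where nothing is present
    empty <- rowSums(presence) == 0L
    presence[empty, 1L] <- 1L

    base_abundance <- exp(stats::rnorm(p, sd = 1))  # shared abundance profile
    counts <- matrix(0L, n, p, dimnames = list(ids, asvs))
    for (i in seq_len(n)) {
      w <- base_abundance * presence[i, ]
      counts[i, ] <- as.integer(stats::rmultinom(1, config$depth, w / sum(w)))
    }
    list(counts = counts,
         metadata = tibble::tibble(sample_id = ids, group = groups))
  })
}
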