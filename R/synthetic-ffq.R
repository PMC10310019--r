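#' Reference composition table for the eight animal foods
#'
#' Grams of animal protein and lipid contributed per portion for the eight
#' foods the food-frequency questionnaire tracks (milk, yogurt, pork, beef,
#' chicken, egg, butter, fish), in the spirit of food-equivalent tables.
#'
#' @return A tibble with columns `food`, `protein_g_per_portion`,
#'   `lipid_g_per_portion`.
#' @export
default_food_composition <- function() {
  tibble::tibble(
    food = c("milk", "yogurt", "pork", "beef", "chicken", "egg", "butter",
             "fish"),
    protein_g_per_portion = c(9, 9, 7, 7, 7, 6, 0, 7),
    lipid_g_per_portion   = c(8, 8, 5, 5, 3, 5, 5, 1.5)
  )
}

#' Generate synthetic food-frequency records with two intake levels
#'
#' Each child receives random portion frequencies for the eight animal
#' foods, scaled so the implied monthly protein intake is drawn from the
#' child's planted level: Normal(`intake_mean_high`, `intake_sd`) for High
#' children, Normal(`intake_mean_low`, `intake_sd`) for Low children. Lipid
#' intake follows from the same frequencies through the composition table,
#' so the two nutrients are naturally correlated, as in real diets.
#'
#' @param config A [synthetic_config()].
#' @param composition Food composition table (default
#'   [default_food_composition()]).
#' @return A list with `ffq` (tibble: `child_id`, `food`,
#'   `portions_per_day`, `portions_per_week`), `composition`, and `truth`
#'   (tibble: `child_id`, `group`, `target_protein_g_month`).
#' @export
generate_ffq <- function(config, composition = default_food_composition()) {
  validate_synthetic_config(config)
  n <- config$n_samples
  n_high <- config$n_samples_high
  groups <- rep(c("H", "L"), c(n_high, n - n_high))
  ids <- sprintf("S%02d", seq_len(n))

  with_seed(config$seed + 2L, {
    records <- vector("list", n)
    targets <- numeric(n)
    for (i in seq_len(n)) {
      mu <- if (groups[i] == "H") config$intake_mean_high else config$intake_mean_low
      target <- max(20, stats::rnorm(1, mu, config$intake_sd))
      targets[i] <- target
      ppd <- stats::rexp(nrow(composition), rate = 4)   # sparse daily portions
      ppw <- stats::rexp(nrow(composition), rate = 1)
      protein0 <- sum((30 * ppd + (30 / 7) * ppw) *
                        composition$protein_g_per_portion)
      scale <- target / protein0
      # butter is protein-free, so varying it independently leaves the planted
      # protein level intact while making the lipid split correlated with but
      # not identical to the protein split
      food_mult <- ifelse(composition$food == "butter",
                          exp(stats::rnorm(nrow(composition), 0, 1)), 1)
      records[[i]] <- tibble::tibble(
        child_id = ids[i],
        food = composition$food,
        portions_per_day = round(ppd * scale * food_mult, 3),
        portions_per_week = round(ppw * scale * food_mult, 3)
      )
    }
    list(ffq = dplyr::bind_rows(records),
         composition = composition,
         truth = tibble::tibble(child_id = ids, group = groups,
                                target_protein_g_month = targets))
  })
}
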