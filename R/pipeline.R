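#' Run the full intake / brain / microbiota connectivity analysis
#'
#' Orchestrates the end-to-end pipeline on a synthetic cohort (or on
#' pre-generated inputs): monthly intake from the food-frequency records
#' and the mean split into High/Low groups with Welch statistics and
#' overlap percentages; qEEG band powers, per band x condition x group MI
#' matrices, MST weights and percent differences; rarefaction, alpha
#' diversity, Gini screening, per-group co-occurrence networks and the
#' gut-microbiota MST comparison. Optionally a random-split null for one
#' EEG band/condition.
#'
#' @param config A [synthetic_config()]; ignored for a stage when the
#'   corresponding input is supplied.
#' @param ffq,eeg,asv Optional pre-generated inputs with the structure
#'   returned by [generate_ffq()], [generate_eeg()] and
#'   [generate_asv_table()].
#' @param nutrient Which intake split labels the EEG/ASV groups
#'   (`"protein"` or `"lipid"`).
#' @param rarefaction_depth Reads per sample after rarefaction (default
#'   `config$min_depth`).
#' @param null_band,null_condition If both non-`NULL`, run
#'   [random_split_null()] for that band/condition with `null_k`
#'   replicates.
#' @param null_k Replicates for the null model (default 199).
#' @param min_clean_seconds Clean-data target passed to the epoch-rejection
#'   stage (lower it for short synthetic recordings).
#' @param out_dir If non-`NULL`, write per-stage CSVs and a JSON summary
#'   there.
#' @return A `gutbrain_run` list with elements `intake`, `intake_stats`,
#'   `overlap`, `band_power`, `eeg_mst` (tibble: band, condition, group,
#'   total_weight, plus percent differences in `eeg_pct`), `alpha`,
#'   `alpha_tests`, `gini`, `gm` (per-group MSTs and percent difference),
#'   and optionally `null`.
#' @export
run_all <- function(config = synthetic_config(),
                    ffq = NULL, eeg = NULL, asv = NULL,
                    nutrient = c("protein", "lipid"),
                    rarefaction_depth = config$min_depth,
                    null_band = NULL, null_condition = NULL,
                    null_k = 199,
                    min_clean_seconds = 0,
                    out_dir = NULL) {
  nutrient <- match.arg(nutrient)
  ffq <- ffq %||% generate_ffq(config)
  eeg <- eeg %||% generate_eeg(config)
  asv <- asv %||% generate_asv_table(config)

  ## --- intake stage -------------------------------------------------------
  intake <- compute_monthly_intake(ffq$ffq, ffq$composition) |>
    add_intake_groups()
  p_sum <- attr(mean_split(intake$protein_g_month), "summary")
  l_sum <- attr(mean_split(intake$lipid_g_month), "summary")
  intake_stats <- dplyr::bind_rows(
    dplyr::mutate(p_sum, nutrient = "protein", .before = 1),
    dplyr::mutate(l_sum, nutrient = "lipid", .before = 1)
  )
  welch <- dplyr::bind_rows(
    dplyr::mutate(
      welch_t(intake$protein_g_month[intake$protein_group == "H"],
              intake$protein_g_month[intake$protein_group == "L"]),
      nutrient = "protein", .before = 1),
    dplyr::mutate(
      welch_t(intake$lipid_g_month[intake$lipid_group == "H"],
              intake$lipid_g_month[intake$lipid_group == "L"]),
      nutrient = "lipid", .before = 1)
  )
  overlap <- dplyr::bind_rows(
    dplyr::mutate(group_overlap(
      sum(intake$protein_group == "H"), sum(intake$lipid_group == "H"),
      sum(intake$protein_group == "H" & intake$lipid_group == "H")),
      level = "high", .before = 1),
    dplyr::mutate(group_overlap(
      sum(intake$protein_group == "L"), sum(intake$lipid_group == "L"),
      sum(intake$protein_group == "L" & intake$lipid_group == "L")),
      level = "low", .before = 1)
  )
  group_col <- paste0(nutrient, "_group")
  group_of <- stats::setNames(as.character(intake[[group_col]]),
                              intake$child_id)

  ## --- brain stage --------------------------------------------------------
  bp <- bandpower_table(eeg$recordings,
                        min_clean_seconds = min_clean_seconds)
  bp$group <- unname(group_of[bp$subject_id])
  combos <- tidyr::expand_grid(band = levels(eeg_bands()$band),
                               condition = unique(bp$condition),
                               group = c("H", "L"))
  eeg_rows <- purrr::pmap_dfr(combos, function(band, condition, group) {
    sub <- bp[bp$group == group, , drop = FALSE]
    mi <- mi_matrix(sub, band = band, condition = condition, group = group)
    res <- mi_mst(mi)
    tibble::tibble(band = band, condition = condition, group = group,
                   n_subjects = mi$n_subjects,
                   total_weight = res$total_weight)
  })
  eeg_pct <- eeg_rows |>
    tidyr::pivot_wider(id_cols = c("band", "condition"),
                       names_from = "group", values_from = "total_weight") |>
    dplyr::mutate(percent_difference =
                    purrr::map2_dbl(.data$H, .data$L,
                                    mst_percent_difference))

  ## --- microbiota stage ---------------------------------------------------
  rare <- rarefy_counts(asv$counts, depth = rarefaction_depth,
                        seed = config$seed + 3L)
  alpha <- alpha_diversity(rare)
  groups_asv <- unname(group_of[rownames(rare)])
  alpha_tests <- alpha_group_test(alpha, groups_asv)
  gini <- gini_importance(rare, groups_asv, n_trees = 200,
                          seed = config$seed + 4L)
  cw_h <- cooccur_weights(rare[groups_asv == "H", , drop = FALSE])
  cw_l <- cooccur_weights(rare[groups_asv == "L", , drop = FALSE])
  gm <- gm_mst(cw_h$weights, cw_l$weights)

  ## --- optional null model ------------------------------------------------
  null <- NULL
  if (!is.null(null_band) && !is.null(null_condition)) {
    n_h <- sum(intake[[group_col]] == "H")
    n_l <- sum(intake[[group_col]] == "L")
    stat_fn <- function(df) {
      mi <- mi_matrix(df, band = null_band, condition = null_condition)
      mi_mst(mi)$total_weight
    }
    bp_null <- bp[order(match(bp$group, c("H", "L"))), , drop = FALSE]
    null <- random_split_null(bp_null, n = min(n_h, n_l), m = max(n_h, n_l),
                              k = null_k, seed = config$seed + 5L,
                              statistic_fn = stat_fn)
  }

  run <- structure(list(
    intake = intake, intake_stats = intake_stats, welch = welch,
    overlap = overlap, band_power = bp, eeg_mst = eeg_rows,
    eeg_pct = eeg_pct, alpha = alpha, alpha_tests = alpha_tests,
    gini = gini, gm = gm, null = null, nutrient = nutrient,
    config = config
  ), class = "gutbrain_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.gutbrain_run <- function(x, ...) {
  cat(sprintf("<gutbrain_run: %d children, nutrient split = %s>\n",
              nrow(x$intake), x$nutrient))
  cat(sprintf("  GM MST percent difference: %.2f%%\n",
              x$gm$percent_difference))
  cat(sprintf("  EEG MST percent difference (mean over bands): %.2f%%\n",
              mean(x$eeg_pct$percent_difference)))
  invisible(x)
}

# serialize a run's tables to CSV plus a JSON summary
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$intake, file.path(out_dir, "intake.csv"))
  readr::write_csv(run$band_power, file.path(out_dir, "band_power.csv"))
  readr::write_csv(run$eeg_mst, file.path(out_dir, "eeg_mst.csv"))
  readr::write_csv(run$eeg_pct, file.path(out_dir, "eeg_pct.csv"))
  readr::write_csv(run$alpha, file.path(out_dir, "alpha_diversity.csv"))
  readr::write_csv(run$gini$importance, file.path(out_dir, "gini.csv"))
  summary <- list(
    nutrient = run$nutrient,
    seed = run$config$seed,
    gm_percent_difference = run$gm$percent_difference,
    gm_weight_high = run$gm$mst_high$total_weight,
    gm_weight_low = run$gm$mst_low$total_weight,
    n_informative_asvs = run$gini$n_informative
  )
  if (!is.null(run$null)) {
    summary$null_p_value <- run$null$p_value
    summary$null_observed <- run$null$observed
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
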