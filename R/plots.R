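#' Boxplot of monthly intake by High/Low group
#'
#' @param intake Tibble from [add_intake_groups()].
#' @param nutrient `"protein"` or `"lipid"`.
#' @return A ggplot.
#' @export
plot_intake <- function(intake, nutrient = c("protein", "lipid")) {
  nutrient <- match.arg(nutrient)
  value_col <- paste0(nutrient, "_g_month")
  group_col <- paste0(nutrient, "_group")
  ggplot2::ggplot(intake, ggplot2::aes(
    x = .data[[group_col]], y = .data[[value_col]],
    fill = .data[[group_col]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = sprintf("%s intake group", tools::toTitleCase(nutrient)),
                  y = "Intake (g/month)") +
    ggplot2::theme_minimal()
}

#' Bar chart of MST weights per band, condition and group
#'
#' @param weights Tibble with columns `band`, `condition`, `group`,
#'   `total_weight` (e.g. the `eeg_mst` element of [run_all()]).
#' @return A ggplot faceted by condition.
#' @export
plot_mst_weights <- function(weights) {
  ggplot2::ggplot(weights, ggplot2::aes(
    x = .data$band, y = .data$total_weight, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "Band", y = "MST total weight", fill = "Intake") +
    ggplot2::theme_minimal()
}

#' Ranked Mean Decrease Gini importances
#'
#' @param importance Tibble from [gini_importance()]'s `importance`
#'   element.
#' @param top Show the `top` highest-ranked ASVs (default 30).
#' @return A ggplot.
#' @export
plot_gini <- function(importance, top = 30) {
  df <- utils::head(dplyr::arrange(importance,
                                   dplyr::desc(.data$mean_decrease_gini)),
                    top)
  df$asv_id <- factor(df$asv_id, levels = rev(df$asv_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_decrease_gini,
                                   y = .data$asv_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean Decrease Gini", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of a random-split null with the observed difference
#'
#' @param object A `random_split_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.random_split_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "Null MST-weight difference (n-set minus m-set)",
                  y = "Replicates",
                  subtitle = sprintf("observed = %.3g, p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot an MST as a dendrogram-free edge diagram
#'
#' Nodes are placed on a circle; tree edges are drawn with width
#' proportional to weight magnitude and colour by sign.
#'
#' @param object An `mst_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mst_result <- function(object, ...) {
  nodes <- sort(unique(c(object$edges$from, object$edges$to)))
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  ed <- object$edges |>
    dplyr::left_join(pos, by = c(from = "node")) |>
    dplyr::left_join(pos, by = c(to = "node"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$weight),
                   colour = .data$weight > 0)) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = 1.1 * .data$x, y = 1.1 * .data$y,
                                    label = .data$node), size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue"),
                                 guide = "none") +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::theme_void()
}
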