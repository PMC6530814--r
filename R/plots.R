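#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_col geom_errorbar geom_tile labs theme_minimal coord_cartesian
#'   scale_fill_gradient2
NULL

#' @export
ggplot2::autoplot

#' Coefficient plot for a fitted expression model
#'
#' Mean coefficient per feature across the outer folds with +/- 1 sd error
#' bars, for the `top_n` features by absolute mean coefficient.
#'
#' @param object A `regscore_fit`.
#' @param top_n How many features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regscore_fit <- function(object, top_n = 25, ...) {
  td <- tidy(object) |>
    filter(.data$term != "(Intercept)") |>
    arrange(desc(abs(.data$estimate))) |>
    utils::head(top_n) |>
    mutate(term = stats::reorder(.data$term, .data$estimate))
  ggplot(td, aes(x = .data$estimate, y = .data$term)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(xmin = .data$estimate - .data$sd,
                      xmax = .data$estimate + .data$sd), width = 0.3) +
    labs(x = "mean coefficient (outer folds)", y = NULL) +
    theme_minimal()
}

#' Precision-recall curve of a regulator ranking
#'
#' @param object A `regscore_pr` from [gold_standard_eval()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regscore_pr <- function(object, ...) {
  pts <- object$points
  ggplot(pts, aes(x = .data$recall, y = .data$precision)) +
    geom_line(color = "steelblue") +
    geom_point(size = 1) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Recall", y = "Precision",
         title = sprintf("AUPR = %.3f", object$aupr)) +
    theme_minimal()
}

#' Heatmap of pairwise score correlations
#'
#' @param pc Result of [pairwise_correlation()].
#' @return A ggplot tile map of the Spearman correlation matrix.
#' @export
plot_pairwise_correlation <- function(pc) {
  cm <- pc$correlations
  df <- tibble(
    a = rep(rownames(cm), times = ncol(cm)),
    b = rep(colnames(cm), each = nrow(cm)),
    rho = as.vector(cm))
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
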