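#' Plot variable inclusion frequencies
#'
#' Horizontal bar chart of the VIFs in report order; the dashed line marks
#' the elimination level `alpha`, the expected inclusion frequency of an
#' independent null covariate.
#'
#' @param report A `stability_report`.
#' @return A ggplot object.
#' @export
plot_vif <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  d <- dplyr::distinct(report$table, .data$term, .keep_all = TRUE)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vif, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 100 * report$alpha, linetype = "dashed") +
    ggplot2::labs(x = "variable inclusion frequency (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pairwise inclusion frequencies
#'
#' Heatmap of the fraction of resamples selecting each pair of terms
#' (diagonal: the VIFs).
#'
#' @param report A `stability_report`.
#' @return A ggplot object.
#' @export
plot_pairwise <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  M <- report$pairwise
  d <- tidyr::expand_grid(term1 = rownames(M), term2 = colnames(M))
  d$freq <- as.vector(t(M))
  ord <- dplyr::distinct(report$table, .data$term)$term
  d$term1 <- factor(d$term1, levels = ord)
  d$term2 <- factor(d$term2, levels = rev(ord))
  ggplot2::ggplot(d, ggplot2::aes(.data$term1, .data$term2, fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1),
                                 name = "pairwise\ninclusion") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object,
                                      type = c("vif", "pairwise"), ...) {
  switch(match.arg(type), vif = plot_vif(object),
         pairwise = plot_pairwise(object))
}

#' @method autoplot performance_table
#' @export
autoplot.performance_table <- function(object, measure = "vif", ...) {
  d <- dplyr::filter(object, .data$measure == !!measure)
  if (measure %in% c("vif", "rcb", "rmsdr")) {
    d$column <- factor(d$column, levels = unique(d$column))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$mean,
                                    colour = .data$scheme,
                                    group = .data$scheme)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_point(ggplot2::aes(y = .data$estimand), colour = "black",
                          shape = 4) +
      ggplot2::labs(y = sprintf("mean estimated %s (x: estimand)", measure),
                    x = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$scheme, y = .data$mean)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$estimand),
                          linetype = "dashed") +
      ggplot2::labs(y = "mean estimated MSF (dashed: estimand)", x = NULL) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
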