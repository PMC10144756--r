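#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for the paired-comparison results
#'
#' `tidy()` returns the Bonferroni-adjusted pairwise comparison table;
#' `glance()` the one-row omnibus result.
#'
#' @param x an `iol_friedman` or `iol_cochran` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.iol_friedman <- function(x, ...) x$pairwise

#' @rdname tidy.iol_friedman
#' @export
glance.iol_friedman <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname tidy.iol_friedman
#' @export
tidy.iol_cochran <- function(x, ...) x$pairwise

#' @rdname tidy.iol_friedman
#' @export
glance.iol_cochran <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @export
print.iol_friedman <- function(x, ...) {
  cat("Friedman test: chi2 =", format(x$statistic, digits = 4),
      "df =", format(x$df, digits = 4), "p =", format(x$p_value, digits = 4), "\n")
  cat("Pairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, ...)
  invisible(x)
}

#' @export
print.iol_cochran <- function(x, ...) {
  cat("Cochran Q:", format(x$statistic, digits = 4),
      "df =", x$df, "p =", format(x$p_value, digits = 4), "\n")
  cat("Pairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, ...)
  invisible(x)
}

#' @export
print.range_scheme <- function(x, ...) {
  cat("Range scheme over", x$variable, "\n")
  cat(" ", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' @export
print.recommendation_table <- function(x, ...) {
  cat("Multi-formula recommendation table (", x$mode, " constants)\n", sep = "")
  print(tidyr::pivot_wider(x$grid, names_from = "al_range", values_from = "cell"), ...)
  cat("AL/K tie-break rows:\n")
  print(x$alk_rows, ...)
  invisible(x)
}

#' Plot methods for trend curves and range comparisons
#'
#' `autoplot.iol_trend()` draws the per-method LOESS trend of prediction
#' errors along the biometric variable; `autoplot.iol_range_comparison()`
#' draws the per-range median absolute error by method.
#'
#' @param object an `iol_trend` or `iol_range_comparison` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iol_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$fitted,
                                       colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = switch(object$variable[1], K = "Mean keratometry (D)",
                 AL = "Axial length (mm)", ALK = "AL/K ratio"),
      y = "Prediction error (D)",
      colour = "Method",
      caption = sprintf("LOESS, span %.2f, degree %d",
                        attr(object, "span"), attr(object, "degree"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.iol_trend
#' @export
autoplot.iol_range_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summaries,
                  ggplot2::aes(x = .data$method, y = .data$medae_d,
                               fill = .data$best_medae)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~range) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Median absolute error (D)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.iol_trend
#' @export
autoplot.recommendation_table <- function(object, ...) {
  grid <- object$grid
  grid$k_range <- factor(grid$k_range, levels = rev(object$k_scheme$labels))
  grid$al_range <- factor(grid$al_range, levels = object$al_scheme$labels)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$al_range, y = .data$k_range,
                                     fill = .data$cell)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cell), size = 3) +
    ggplot2::labs(x = "Axial length range", y = "Keratometry range",
                  fill = NULL,
                  title = paste0("Suggested formula (",
                                 object$mode, " constants)")) +
    ggplot2::theme_minimal()
}
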