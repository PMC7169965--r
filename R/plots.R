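#' Distribution of prion-like run-parse scores
#'
#' Histogram of `best_llr` in bins of width 10 (labelled by bin
#' midpoints), coloured by family when a `family` column is present.
#'
#' @param rows Family-annotation tibble.
#' @param binwidth Bin width in score units (default 10).
#' @return A ggplot object.
#' @export
plot_llr_distribution <- function(rows, binwidth = 10) {
  rows <- tibble::as_tibble(rows)
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$best_llr))
  if ("family" %in% names(rows)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$family),
      binwidth = binwidth, boundary = 0, position = "dodge")
  } else {
    p <- p + ggplot2::geom_histogram(binwidth = binwidth, boundary = 0)
  }
  p +
    ggplot2::labs(x = "prion-like LLR score", y = "proteins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Intrinsic disorder versus prion-like score
#'
#' Scatter plot of a per-protein disorder percentage against the
#' run-parse LLR, with a linear fit per family.
#'
#' @param rows Family-annotation tibble with a disorder column.
#' @param disorder Column name holding the disorder percentage (default
#'   `"pct_disorder_a"`).
#' @return A ggplot object.
#' @export
plot_disorder_vs_llr <- function(rows, disorder = "pct_disorder_a") {
  rows <- tibble::as_tibble(rows)
  if (!disorder %in% names(rows)) {
    stop("rows lack disorder column '", disorder, "'", call. = FALSE)
  }
  aes <- if ("family" %in% names(rows)) {
    ggplot2::aes(x = .data$best_llr, y = .data[[disorder]],
                 colour = .data$family)
  } else {
    ggplot2::aes(x = .data$best_llr, y = .data[[disorder]])
  }
  ggplot2::ggplot(rows, aes) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "prion-like LLR score", y = "% disorder",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of RRM-domain counts
#'
#' @param rows Family-annotation tibble with `n_rrm`.
#' @return A ggplot object.
#' @export
plot_rrm_counts <- function(rows) {
  rows <- tibble::as_tibble(rows)
  aes <- if ("family" %in% names(rows)) {
    ggplot2::aes(x = factor(.data$n_rrm), fill = .data$family)
  } else {
    ggplot2::aes(x = factor(.data$n_rrm))
  }
  ggplot2::ggplot(rows, aes) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "RRM domains per protein", y = "proteins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a family summary
#'
#' Grouped bars of the per-group fractions of a [summarize_family()]
#' result.
#'
#' @param object A `family_summary` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot.family_summary
#' @exportS3Method ggplot2::autoplot
autoplot.family_summary <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$statistic, y = .data$value,
                                 fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction / count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
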