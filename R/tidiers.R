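# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-genus score statistics of a model
#'
#' @param x A `genus_stats` or `tax_machine` object.
#' @param ... Unused.
#' @return A tibble with one row per genus: `genus`, `n`, `p_bar`,
#'   `s_raw`, `s_size`, `s_bar`.
#' @export
tidy.genus_stats <- function(x, ...) {
  x$genus_table
}

#' @rdname tidy.genus_stats
#' @export
tidy.tax_machine <- function(x, ...) {
  tidy(x$stats)
}

#' Tidy the length-normalization coefficients
#'
#' @param x A `length_norm` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted regression (`mean`, `sd`)
#'   and columns `component`, `intercept`, `slope`.
#' @export
tidy.length_norm <- function(x, ...) {
  tibble::tibble(
    component = c("mean", "sd"),
    intercept = c(x$mean_coef[1], x$sd_coef[1]),
    slope = c(x$mean_coef[2], x$sd_coef[2])
  )
}

#' One-row summary of a trained classification stack
#'
#' @param x A `tax_machine` object.
#' @param ... Unused.
#' @return A one-row tibble: training-set name, `K`, `pseudo`, numbers of
#'   taxa and sequences, fitted length range and ECDF size.
#' @export
glance.tax_machine <- function(x, ...) {
  tibble::tibble(
    name = x$metadata$name,
    K = x$metadata$K,
    pseudo = x$metadata$pseudo,
    n_taxa = x$metadata$n_taxa,
    n_sequences = x$metadata$n_sequences,
    length_min = x$norm$fit_range[1],
    length_max = x$norm$fit_range[2],
    n_r_train = length(x$stats$r_train)
  )
}

#' Plot the length-normalization fit
#'
#' Scatter of maximum posterior log2-probability against fragment length
#' with the fitted mean line and a +/- 2 SD band.
#'
#' @param object A `length_norm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.length_norm <- function(object, ...) {
  df <- object$fragments
  rng <- seq(object$fit_range[1], object$fit_range[2], length.out = 100)
  band <- tibble::tibble(
    length = rng,
    mid = object$mean_coef[1] + object$mean_coef[2] * rng,
    sd = object$sd_coef[1] + object$sd_coef[2] * rng
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$p1)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$length, ymin = .data$mid - 2 * .data$sd,
                   ymax = .data$mid + 2 * .data$sd),
      inherit.aes = FALSE, alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(
      data = band, ggplot2::aes(x = .data$length, y = .data$mid),
      inherit.aes = FALSE, colour = "steelblue") +
    ggplot2::labs(x = "fragment length (bases)",
                  y = "max posterior log2-probability")
}

#' Plot genus SD against genus size with the loess smooth
#'
#' The analogue of plotting raw per-genus SDs (points) against genus size
#' with the smoothed size-specific SD curve used for shrinkage.
#'
#' @param object A `genus_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genus_stats <- function(object, ...) {
  gt <- object$genus_table[!is.na(object$genus_table$s_raw), ]
  ggplot2::ggplot(gt, ggplot2::aes(x = .data$n, y = .data$s_raw)) +
    ggplot2::geom_point(shape = 1, colour = "grey50") +
    ggplot2::geom_point(
      data = object$size_table,
      ggplot2::aes(x = .data$size, y = .data$smooth_sd),
      inherit.aes = FALSE, shape = 15, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genus size (sequences)",
                  y = "SD of normalized log-probability")
}

#' Histogram of r-scores from classification records
#'
#' @param records A tibble from [classify_with_uncertainty()].
#' @param binwidth Histogram bin width (r-score units).
#' @return A ggplot object.
#' @export
plot_rscores <- function(records, binwidth = 0.5) {
  df <- records[!is.na(records$r_score), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_score)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "r-score", y = "sequences")
}
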