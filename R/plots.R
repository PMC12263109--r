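# Plotting is optional sugar over the tabular results; ggplot2 is only
# suggested, so every function checks for it at call time.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
}

#' Plot capture curves
#'
#' @param curves A `capture_curve` data frame, or the `curves` element of a
#'   [compare_strategies()] result (long format with a `strategy` column).
#' @param baseline_n Optional candidate-list length; when given, the
#'   random-guess baseline `k / n` is drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_capture_curve <- function(curves, baseline_n = NULL) {
  .need_ggplot()
  df <- as.data.frame(curves)
  if (!"strategy" %in% names(df)) df$strategy <- "observed"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = k, y = proportion,
                                        colour = strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(df$k)) +
    ggplot2::labs(x = "rank threshold k",
                  y = "proportion of causal genes captured",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
  if (!is.null(baseline_n)) {
    bk <- unique(df$k)
    p <- p + ggplot2::geom_line(
      data = data.frame(k = bk, proportion = random_baseline(baseline_n, bk),
                        strategy = "random guess"),
      linetype = "dashed")
  }
  p
}

#' Plot mean causal rank against input position
#'
#' @param pb A [positional_bias()] result.
#' @return A ggplot object.
#' @export
plot_positional_bias <- function(pb) {
  .need_ggplot()
  stopifnot(inherits(pb, "positional_bias"))
  ggplot2::ggplot(pb$per_position,
                  ggplot2::aes(x = position, y = mean_rank)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "causal gene position in input list",
                  y = "mean final rank")
}
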