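#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_rect
#'   geom_hline geom_col labs theme_minimal facet_wrap geom_ribbon
NULL

#' @export
ggplot2::autoplot

#' Plot a stride time series
#'
#' Stride length against onset time, with detected turn gaps shaded — the
#' visual check used to spot non-detected turns: a proper export shows a
#' regular pattern of gaps; a missed turn shows drastically short strides
#' where a gap should be.
#'
#' @param object A [gait_trial()].
#' @param gap_factor Passed to [detect_turn_gaps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_trial <- function(object, gap_factor = 1.5, ...) {
  turns <- detect_turn_gaps(object, gap_factor = gap_factor)
  p <- ggplot(as_tibble(object),
              aes(x = .data$onset_s, y = .data$stride_length_pct_stature))
  if (nrow(turns) > 0) {
    p <- p + geom_rect(
      data = turns, inherit.aes = FALSE,
      aes(xmin = .data$gap_start_s, xmax = .data$gap_end_s,
          ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6
    )
  }
  p +
    geom_point(aes(colour = .data$periturn_tag)) +
    labs(
      x = "Time from trial start [s]",
      y = "Stride length [% stature]",
      colour = "Peri-turn tag",
      title = sprintf("Stride series, subject %s (%d turn gaps)",
                      object$subject_id[[1]], nrow(turns))
    ) +
    theme_minimal()
}

#' Plot a convergence profile
#'
#' Pearson R between the cumulative statistic at n strides and its value
#' at the reference stride count, with the reliability criterion drawn as
#' a horizontal line.
#'
#' @param object A [convergence_profile()] result.
#' @param threshold Criterion line (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.convergence_result <- function(object, threshold = 0.8, ...) {
  ggplot(as_tibble(object), aes(x = .data$n, y = .data$r)) +
    geom_hline(yintercept = threshold, linetype = "dashed",
               colour = "grey40") +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "Gait cycles (n)",
      y = sprintf("Pearson R vs value at stride %d",
                  attr(object, "n_max", exact = TRUE)),
      title = sprintf("Convergence of %s",
                      attr(object, "statistic", exact = TRUE))
    ) +
    theme_minimal()
}

#' Plot a probability-density histogram
#'
#' Density bars with the fitted normal curve superimposed, the standard
#' display for judging skew of pooled peri-turn stride values.
#'
#' @param object A [density_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_histogram <- function(object, ...) {
  p <- ggplot(object$bins) +
    geom_rect(aes(xmin = .data$edge_lo, xmax = .data$edge_hi,
                  ymin = 0, ymax = .data$density),
              fill = "steelblue", colour = "white") +
    labs(x = "Value", y = "Probability density") +
    theme_minimal()
  if (object$sd > 0) {
    lo <- min(object$bins$edge_lo)
    hi <- max(object$bins$edge_hi)
    grid <- tibble(
      x = seq(lo, hi, length.out = 200),
      y = stats::dnorm(seq(lo, hi, length.out = 200),
                       object$mean, object$sd)
    )
    p <- p + geom_line(data = grid, aes(x = .data$x, y = .data$y),
                       colour = "black")
  }
  p
}

#' Group-level cumulative CoV curves
#'
#' Mean cumulative CoV per group against stride count with a 95%
#' confidence ribbon, the display that reveals whether accumulating more
#' strides stabilizes or (through peri-turn strides) inflates the
#' variability estimate.
#'
#' @param cumulative A long cumulative table from [cohort_cumulative()] or
#'   `run_pipeline()$cumulative`.
#' @param parameter `"stride_length"` or `"stride_time"`.
#' @return A ggplot object.
#' @export
plot_cumulative_cov <- function(cumulative,
                                parameter = c("stride_length",
                                              "stride_time")) {
  parameter <- match.arg(parameter)
  dat <- cumulative |>
    filter(.data$parameter == !!parameter) |>
    group_by(.data$group, .data$n) |>
    summarise(
      m = mean(.data$cum_cov),
      se = stats::sd(.data$cum_cov) / sqrt(n()),
      .groups = "drop"
    )
  ggplot(dat, aes(x = .data$n, y = .data$m, colour = .data$group,
                  fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$m - 1.96 * .data$se,
                    ymax = .data$m + 1.96 * .data$se),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "Gait cycles (n)", y = "Cumulative CoV [%]",
         title = sprintf("Cumulative CoV of %s", parameter)) +
    theme_minimal()
}

#' Per-segment CoV by group
#'
#' Group means with SD whiskers of the segment CoVs, per segment and
#' parameter — the consistency display that ICC values annotate.
#'
#' @param segment_stats `run_pipeline()$segment_stats`.
#' @return A ggplot object.
#' @export
plot_segment_cov <- function(segment_stats) {
  dat <- segment_stats |>
    group_by(.data$group, .data$parameter, .data$segment_id) |>
    summarise(m = mean(.data$cov), s = stats::sd(.data$cov),
              .groups = "drop")
  ggplot(dat, aes(x = factor(.data$segment_id), y = .data$m,
                  colour = .data$group, group = .data$group)) +
    geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      aes(ymin = .data$m - .data$s, ymax = .data$m + .data$s),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)
    ) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "Segment", y = "CoV [%]") +
    theme_minimal()
}
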