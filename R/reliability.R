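#' Two-way random-effects, single-measure intraclass correlation
#'
#' ICC(2,1) from the two-way random-effects ANOVA decomposition, treating
#' walking segments as repeated measurements of each subject:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the mean squares for
#' rows (subjects), columns (segments) and residual error, \eqn{n} the
#' number of subjects and \eqn{k} the number of segments. The mean squares
#' are computed from explicit sums of squares and returned for audit.
#'
#' @param mat Numeric matrix, subjects in rows, segments in columns; at
#'   least 2 x 2, no missing cells (drop incomplete subjects beforehand).
#' @return An object of class `icc_result`: list with `icc`, `n_subjects`,
#'   `k_segments`, `msr`, `msc`, `mse`, and `band` (see [icc_band()]).
#' @seealso [icc_band()], [tidy.icc_result()]
#' @examples
#' m <- matrix(rnorm(18, mean = rep(1:6, 3)), nrow = 6)
#' icc_two_way_random_single(m)
#' @export
icc_two_way_random_single <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    abort("Missing cells; drop incomplete subjects before computing ICC.")
  }
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) abort("Need at least 2 subjects and 2 segments.")
  grand <- mean(mat)
  ss_total <- sum((mat - grand)^2)
  if (ss_total == 0) abort("Degenerate: all cells are equal.")
  row_means <- rowMeans(mat)
  col_means <- colMeans(mat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((mat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(
    list(
      icc = icc, n_subjects = n, k_segments = k,
      msr = msr, msc = msc, mse = mse, band = icc_band(icc)
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.4f (%s), %d subjects x %d segments\nMS rows %.4g, MS columns %.4g, MS error %.4g\n",
    x$icc, x$band, x$n_subjects, x$k_segments, x$msr, x$msc, x$mse
  ))
  invisible(x)
}

#' Interpretation band for an ICC value
#'
#' Conventional qualitative bands: below 0.4 is `"poor"`, 0.4 to 0.8
#' (both ends inclusive) `"fair_to_good"`, above 0.8 `"excellent"`.
#'
#' @param icc Numeric ICC value(s).
#' @return Character vector of band labels.
#' @examples
#' icc_band(c(0.3, 0.8, 0.95))
#' @export
icc_band <- function(icc) {
  ifelse(icc < 0.4, "poor",
         ifelse(icc <= 0.8, "fair_to_good", "excellent"))
}

#' Correlation of cumulative statistics with their final value
#'
#' For each window size `n`, computes the Pearson correlation across
#' subjects between the cumulative statistic at `n` strides and the same
#' statistic at the reference stride count `N_max`. By construction the
#' profile ends at exactly 1 (the statistic correlates perfectly with
#' itself); how early it rises above a reliability criterion tells how few
#' strides suffice for a stable estimate.
#'
#' @param data A long cumulative table as produced by
#'   [cohort_cumulative()] (or any tibble with `subject_id`, `n`, and the
#'   statistic column), already filtered to one parameter.
#' @param statistic `"cum_mean"` or `"cum_cov"`.
#' @return An object of class `convergence_result`: tibble with columns
#'   `n` and `r`, carrying `statistic` and `n_max` attributes.
#' @examples
#' coh <- generate_cohort(cohort_profiles("HE"), c(HE = 12), seed = 4)
#' cum <- cohort_cumulative(lapply(coh, segment_by_turns), n_max = 40)
#' cp <- convergence_profile(dplyr::filter(cum, parameter == "stride_length"),
#'                           "cum_mean")
#' required_stride_count(cp)
#' @export
convergence_profile <- function(data, statistic = c("cum_mean", "cum_cov")) {
  statistic <- match.arg(statistic)
  if (!all(c("subject_id", "n", statistic) %in% names(data))) {
    abort("`data` needs columns subject_id, n and the chosen statistic.")
  }
  if ("parameter" %in% names(data) &&
      length(unique(data$parameter)) > 1) {
    abort("Filter `data` to a single parameter first.")
  }
  wide <- data |>
    select("subject_id", "n", dplyr::all_of(statistic)) |>
    tidyr::pivot_wider(names_from = "n", values_from = dplyr::all_of(statistic))
  if (anyNA(wide)) {
    abort("All subjects must share the same n grid (no missing windows).")
  }
  if (nrow(wide) < 3) abort("Need at least 3 subjects.")
  ns <- as.integer(names(wide)[-1])
  n_max <- max(ns)
  final <- wide[[as.character(n_max)]]
  if (stats::sd(final) == 0) {
    abort("Undefined correlation: no between-subject variance at N_max.")
  }
  r <- vapply(as.character(ns), function(nm) {
    stats::cor(wide[[nm]], final)
  }, numeric(1))
  r[ns == n_max] <- 1 # self-correlation, exact by definition
  out <- tibble(n = ns, r = unname(r))
  structure(
    out,
    statistic = statistic,
    n_max = n_max,
    class = c("convergence_result", class(tibble()))
  )
}

#' Minimum stride count for a reliable estimate
#'
#' The smallest window size at which the convergence profile exceeds the
#' reliability criterion (`R > threshold`, default 0.8). The default
#' first-crossing rule returns the first such `n` regardless of later
#' dips; `sustained = TRUE` instead requires the profile to stay above the
#' threshold from `n` through `N_max`.
#'
#' @param result A [convergence_profile()] result.
#' @param threshold Criterion on Pearson R (default 0.8).
#' @param sustained Require sustained exceedance (default `FALSE`).
#' @return The required stride count (integer). Always at most `N_max`,
#'   where the profile equals 1.
#' @export
required_stride_count <- function(result, threshold = 0.8,
                                  sustained = FALSE) {
  above <- result$r > threshold
  if (sustained) {
    # last run up to n_max: smallest n from which all later r stay above
    ok <- rev(cumprod(rev(above))) > 0
    idx <- which(ok)[1]
  } else {
    idx <- which(above)[1]
  }
  if (is.na(idx)) return(NA_integer_)
  as.integer(result$n[idx])
}

#' Count subjects above a CoV cut-off
#'
#' Counts coefficient-of-variation values strictly greater than the
#' cut-off; 2.6% is the literature cut-off for physiological stride-time
#' variability, above which variability is classed as increased.
#'
#' @param cov_values Numeric vector of per-subject CoVs (percent).
#' @param cutoff CoV cut-off in percent (default 2.6).
#' @return A one-row tibble: `n_above`, `n_total`, `fraction`.
#' @examples
#' classify_above_cutoff(c(2.7, 2.6, 1.9))
#' @export
classify_above_cutoff <- function(cov_values, cutoff = 2.6) {
  n_total <- length(cov_values)
  n_above <- sum(cov_values > cutoff)
  tibble(
    n_above = n_above,
    n_total = n_total,
    fraction = if (n_total > 0) n_above / n_total else NA_real_
  )
}
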