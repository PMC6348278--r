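#' Coefficient of variation, in percent
#'
#' `(sample SD / mean) * 100`, the standard magnitude measure of gait
#' variability. The sample SD (`n - 1` denominator) is used throughout the
#' package.
#'
#' @param values Numeric vector of at least two positive values.
#' @return CoV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # sample SD 1, mean 2 -> 50
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    abort("CoV is undefined for fewer than 2 values.")
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    abort("CoV is undefined for a non-positive mean.")
  }
  100 * stats::sd(values) / m
}

#' Cumulative mean and CoV over the first n strides
#'
#' Evaluates, for every window size `n` from `n_min` to `n_max`, the mean
#' and coefficient of variation of the first `n` values of an ordered
#' stride sequence. These cumulative profiles show how quickly a
#' variability estimate stabilizes as strides accumulate; a CoV needs at
#' least three values to be meaningfully defined, hence the default lower
#' bound.
#'
#' @param values Ordered numeric vector (the post-excision stride sequence
#'   of one parameter, in onset order).
#' @param n_min Smallest window (default 3).
#' @param n_max Largest window; the caller fixes the analysis reference
#'   (40 strides under standard excision, 32 under generous excision).
#'   Defaults to `length(values)`.
#' @return A tibble of class `cumulative_series` with columns `n`,
#'   `cum_mean`, `cum_cov`. The final row reproduces the whole-window
#'   statistics exactly.
#' @examples
#' x <- rnorm(40, 100, 2)
#' cs <- cumulative_series(x)
#' tail(cs, 1)$cum_cov == coefficient_of_variation(x) # final row is exact
#' @export
cumulative_series <- function(values, n_min = 3L, n_max = length(values)) {
  n_min <- as.integer(n_min)
  n_max <- as.integer(n_max)
  if (n_min < 2L) abort("`n_min` must be at least 2.")
  if (n_max < n_min) abort("`n_max` must be >= `n_min`.")
  if (length(values) < n_max) {
    abort(sprintf("Need %d values for the cumulative reference, got %d.",
                  n_max, length(values)))
  }
  ns <- n_min:n_max
  out <- tibble(
    n = ns,
    cum_mean = vapply(ns, function(n) mean(values[1:n]), numeric(1)),
    cum_cov = vapply(ns, function(n) coefficient_of_variation(values[1:n]),
                     numeric(1))
  )
  class(out) <- c("cumulative_series", class(out))
  out
}

#' Cumulative series for a whole cohort
#'
#' Convenience wrapper computing [cumulative_series()] for stride length
#' and stride time of every trial in a cohort, over the concatenated
#' post-excision stride sequence in onset order (turn gaps contribute no
#' strides). Trials with fewer than `n_max` analyzed strides are dropped
#' with a warning.
#'
#' @param cohort A list of [segment_by_turns()] results.
#' @param width Extra excision width passed to [apply_extra_excision()].
#' @param n_min,n_max Window bounds (see [cumulative_series()]).
#' @return A long tibble: `subject_id`, `group`, `parameter`
#'   (`"stride_length"` / `"stride_time"`), `n`, `cum_mean`, `cum_cov`.
#' @export
cohort_cumulative <- function(cohort, width = 0L, n_min = 3L, n_max = 40L) {
  if (inherits(cohort, "segmented_trial")) cohort <- list(cohort)
  rows <- purrr::map(cohort, function(seg) {
    strides <- apply_extra_excision(seg, width = width)
    if (nrow(strides) < n_max) {
      warn(sprintf("Trial %s has %d analyzed strides (< %d); dropped.",
                   strides$subject_id[1] %||% "?", nrow(strides), n_max))
      return(NULL)
    }
    per_param <- function(col, label) {
      cs <- cumulative_series(strides[[col]], n_min = n_min, n_max = n_max)
      mutate(as_tibble(cs),
             subject_id = strides$subject_id[[1]],
             group = strides$group[[1]],
             parameter = label, .before = 1)
    }
    bind_rows(
      per_param("stride_length_pct_stature", "stride_length"),
      per_param("stride_time_s", "stride_time")
    )
  })
  bind_rows(rows)
}

#' Per-segment mean and CoV
#'
#' Computes the mean and coefficient of variation of one gait parameter
#' within each straight-walking segment of a trial, treating the segments
#' as repeated measurements of the same quantity. Segments with fewer than
#' three strides are skipped with a warning. The spread of segment CoVs —
#' the maximum minus minimum — is attached as the `cov_range` attribute,
#' since absolute agreement across segments can be tight even when
#' rank-based consistency (ICC) is poor.
#'
#' @param seg A [segment_by_turns()] result (optionally after
#'   [apply_extra_excision()]; any tibble with `segment_id` works).
#' @param parameter `"stride_length"` or `"stride_time"`.
#' @return A tibble with columns `segment_id`, `n_strides`, `mean`, `cov`,
#'   plus attribute `cov_range`.
#' @export
per_segment_stats <- function(seg,
                              parameter = c("stride_length", "stride_time")) {
  parameter <- match.arg(parameter)
  col <- switch(parameter,
                stride_length = "stride_length_pct_stature",
                stride_time = "stride_time_s")
  tbl <- filter(as_tibble(seg), !is.na(.data$segment_id))
  counts <- tbl |> group_by(.data$segment_id) |> summarise(n = n())
  short <- counts$segment_id[counts$n < 3]
  if (length(short) > 0) {
    warn(sprintf("Skipping %d segment(s) with < 3 strides.", length(short)))
    tbl <- filter(tbl, !.data$segment_id %in% short)
  }
  if (nrow(tbl) == 0) abort("No segment has 3 or more strides.")
  out <- tbl |>
    group_by(segment_id = .data$segment_id) |>
    summarise(
      n_strides = n(),
      mean = mean(.data[[col]]),
      cov = coefficient_of_variation(.data[[col]]),
      .groups = "drop"
    )
  attr(out, "cov_range") <- max(out$cov) - min(out$cov)
  attr(out, "parameter") <- parameter
  out
}

#' Reference means for peri-turn normalization
#'
#' The individual reference against which peri-turn strides are expressed:
#' the mean stride length and stride time over the subject's first `n_ref`
#' analyzed strides (peri-turn strides included — they are part of the
#' exported window).
#'
#' @param cohort A list of [segment_by_turns()] results.
#' @param n_ref Number of leading analyzed strides in the reference
#'   (default 40; use 32 under generous excision).
#' @param width Extra excision width defining the analyzed sequence.
#' @return A tibble: `subject_id`, `ref_length_pct`, `ref_time_s`.
#' @export
periturn_reference <- function(cohort, n_ref = 40L, width = 0L) {
  if (inherits(cohort, "segmented_trial")) cohort <- list(cohort)
  rows <- purrr::map(cohort, function(seg) {
    strides <- apply_extra_excision(seg, width = width)
    use <- utils::head(strides, n_ref)
    tibble(
      subject_id = use$subject_id[[1]],
      ref_length_pct = mean(use$stride_length_pct_stature),
      ref_time_s = mean(use$stride_time_s)
    )
  })
  bind_rows(rows)
}

#' Normalize peri-turn strides to the individual mean
#'
#' Expresses each extracted peri-turn stride as a percentage of its
#' subject's reference mean, making strides poolable across subjects of
#' different size and tempo: a stride exactly at the subject's average maps
#' to 100%.
#'
#' @param periturn Output of [extract_periturn_strides()].
#' @param reference Output of [periturn_reference()] for the same cohort.
#' @return `periturn` with added columns `rel_length_pct` and
#'   `rel_time_pct` (percent of the individual reference).
#' @export
normalize_periturn <- function(periturn, reference) {
  if (nrow(periturn) == 0) {
    return(mutate(periturn, rel_length_pct = numeric(0),
                  rel_time_pct = numeric(0)))
  }
  if (any(reference$ref_length_pct <= 0) || any(reference$ref_time_s <= 0)) {
    abort("Reference means must be positive.")
  }
  out <- left_join(periturn, reference, by = "subject_id")
  if (anyNA(out$ref_length_pct)) {
    abort("Some peri-turn subjects are missing from `reference`.")
  }
  out |>
    mutate(
      rel_length_pct = 100 * .data$stride_length_pct_stature /
        .data$ref_length_pct,
      rel_time_pct = 100 * .data$stride_time_s / .data$ref_time_s
    ) |>
    select(-"ref_length_pct", -"ref_time_s")
}

#' Paired t-test on a vector of differences
#'
#' The one-sample t statistic on paired differences,
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom with a
#' two-sided p-value; used to test whether peri-turn strides deviate
#' systematically from the individual average (differences of the
#' normalized values from 100%).
#'
#' @param differences Numeric vector of paired differences (>= 2, with
#'   non-zero spread).
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p.value`.
#' @examples
#' paired_t_test(c(1, 2, 3)) # t = 2 / (1 / sqrt(3)) = 3.464
#' @export
paired_t_test <- function(differences) {
  n <- length(differences)
  if (n < 2) abort("Need at least 2 differences.")
  s <- stats::sd(differences)
  if (s == 0) abort("Degenerate test: the differences have zero variance.")
  t_stat <- mean(differences) / (s / sqrt(n))
  df <- n - 1
  tibble(
    estimate = mean(differences),
    statistic = t_stat,
    df = df,
    p.value = 2 * stats::pt(-abs(t_stat), df)
  )
}

#' Peri-turn comparison against the individual average
#'
#' For each side (before/after the turn) and parameter (stride length /
#' stride time), summarizes the normalized peri-turn strides and tests
#' their deviation from the 100% individual reference with a paired
#' t-test.
#'
#' @param normalized Output of [normalize_periturn()].
#' @return A tibble of class `periturn_comparison`, one row per
#'   `position` x `parameter`: `n`, `rel_mean_pct`, `rel_sd_pct`,
#'   `statistic`, `df`, `p.value`.
#' @export
periturn_comparison <- function(normalized) {
  long <- normalized |>
    tidyr::pivot_longer(
      c("rel_length_pct", "rel_time_pct"),
      names_to = "parameter", values_to = "rel_pct"
    ) |>
    mutate(parameter = ifelse(.data$parameter == "rel_length_pct",
                              "stride_length", "stride_time"))
  out <- long |>
    group_by(.data$position, .data$parameter) |>
    summarise(
      n = n(),
      rel_mean_pct = mean(.data$rel_pct),
      rel_sd_pct = stats::sd(.data$rel_pct),
      test = list(paired_t_test(.data$rel_pct - 100)),
      .groups = "drop"
    ) |>
    tidyr::unnest("test") |>
    select(-"estimate")
  class(out) <- c("periturn_comparison", class(out))
  out
}

#' Probability-density histogram with a normal overlay
#'
#' Bins a sample into `n_bins` equal-width bins and normalizes the counts
#' to a probability density, so cohorts of very different size (say 248
#' versus 648 pooled strides) are directly comparable: each histogram
#' carries unit mass. The sample mean and SD parameterize the normal
#' density conventionally superimposed to visualize skew. A degenerate
#' all-equal sample yields a single spike bin with SD 0 and no overlay.
#'
#' @param values Numeric vector (>= 2 values).
#' @param n_bins Number of equal-width bins over the sample range
#'   (default 20).
#' @return An object of class `density_histogram`: list with `bins` (a
#'   tibble `edge_lo`, `edge_hi`, `count`, `density`), `mean`, `sd`, `n`.
#' @export
density_histogram <- function(values, n_bins = 20L) {
  if (length(values) < 2) abort("Need at least 2 values.")
  rng <- range(values)
  if (diff(rng) == 0) {
    bins <- tibble(
      edge_lo = rng[1] - 0.5, edge_hi = rng[1] + 0.5,
      count = length(values), density = 1
    )
    return(structure(
      list(bins = bins, mean = rng[1], sd = 0, n = length(values)),
      class = "density_histogram"
    ))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  structure(
    list(
      bins = tibble(
        edge_lo = utils::head(h$breaks, -1),
        edge_hi = utils::tail(h$breaks, -1),
        count = h$counts,
        density = h$density
      ),
      mean = mean(values),
      sd = stats::sd(values),
      n = length(values)
    ),
    class = "density_histogram"
  )
}

#' @export
print.density_histogram <- function(x, ...) {
  cat(sprintf(
    "<density_histogram> n = %d, %d bins, fitted normal mean %.3f sd %.3f\n",
    x$n, nrow(x$bins), x$mean, x$sd
  ))
  invisible(x)
}
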