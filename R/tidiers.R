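#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ICC result
#'
#' `tidy()` returns the ANOVA mean squares underlying the ICC, one row per
#' variance source; `glance()` returns the one-row model summary.
#'
#' @param x An [icc_two_way_random_single()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(
    term = c("subjects", "segments", "error"),
    df = c(x$n_subjects - 1L, x$k_segments - 1L,
           (x$n_subjects - 1L) * (x$k_segments - 1L)),
    mean_square = c(x$msr, x$msc, x$mse)
  )
}

#' @rdname tidy.icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble(
    icc = x$icc, band = x$band,
    n_subjects = x$n_subjects, k_segments = x$k_segments
  )
}

#' Tidy a convergence profile
#'
#' `tidy()` returns the per-stride correlation profile; `glance()` the
#' one-row summary including the required stride count at the given
#' threshold.
#'
#' @param x A [convergence_profile()] result.
#' @param threshold Reliability criterion used for
#'   [required_stride_count()] in `glance()` (default 0.8).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.convergence_result <- function(x, ...) {
  tibble(
    statistic = attr(x, "statistic", exact = TRUE),
    n = x$n, r = x$r
  )
}

#' @rdname tidy.convergence_result
#' @export
glance.convergence_result <- function(x, threshold = 0.8, ...) {
  tibble(
    statistic = attr(x, "statistic", exact = TRUE),
    n_max = attr(x, "n_max", exact = TRUE),
    n_required = required_stride_count(x, threshold = threshold),
    threshold = threshold,
    r_min = min(x$r)
  )
}
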