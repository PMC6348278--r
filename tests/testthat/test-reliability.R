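test_that("ICC(2,1) agrees with the aov-based ANOVA oracle", {
  withr::with_seed(11, {
    for (dims in list(c(6, 3), c(10, 5), c(50, 5), c(4, 2), c(30, 3))) {
      mat <- matrix(rnorm(prod(dims), mean = rep(rnorm(dims[1], sd = 2),
                                                 dims[2])),
                    nrow = dims[1])
      res <- icc_two_way_random_single(mat)
      expect_equal(res$icc, icc21_oracle(mat), tolerance = 1e-10)
      expect_equal(res$n_subjects, dims[1])
      expect_equal(res$k_segments, dims[2])
    }
  })
})

test_that("ICC limits behave correctly", {
  # identical columns, non-constant rows: perfect agreement
  base <- matrix(rep(1:6, 3), nrow = 6)
  expect_equal(icc_two_way_random_single(base)$icc, 1)

  # all-equal matrix is degenerate; missing cells are refused
  expect_error(icc_two_way_random_single(matrix(5, 4, 3)), "Degenerate")
  m <- base; m[2, 2] <- NA
  expect_error(icc_two_way_random_single(m), "Missing cells")
  expect_error(icc_two_way_random_single(matrix(1:3, ncol = 1)),
               "at least 2")

  # growing i.i.d. noise on identical columns drives ICC toward 0
  withr::with_seed(21, {
    noise <- matrix(rnorm(18), 6, 3)
    iccs <- vapply(c(0.1, 1, 10, 100), function(s) {
      icc_two_way_random_single(base + s * noise)$icc
    }, numeric(1))
    expect_true(all(diff(iccs) < 0))
    expect_lt(iccs[4], 0.1)
  })
})

test_that("ICC deflates when between-subject spread shrinks", {
  # same within-subject noise, narrower spread of true values -> lower ICC
  withr::with_seed(33, {
    true_wide <- rnorm(40, 3, 1.5)
    true_narrow <- rnorm(40, 3, 0.3)
    noise <- matrix(rnorm(40 * 3, sd = 0.5), 40, 3)
    icc_wide <- icc_two_way_random_single(true_wide + noise)$icc
    icc_narrow <- icc_two_way_random_single(true_narrow + noise)$icc
    expect_lt(icc_narrow, icc_wide)
  })
})

test_that("ICC bands follow the 0.4 / 0.8 convention", {
  expect_equal(icc_band(0.3), "poor")
  expect_equal(icc_band(0.4), "fair_to_good")
  expect_equal(icc_band(0.8), "fair_to_good") # upper bound inclusive
  expect_equal(icc_band(0.95), "excellent")
  expect_equal(icc_band(c(-0.2, 0.5, 0.9)),
               c("poor", "fair_to_good", "excellent"))
})

test_that("convergence profiles end at exactly 1 and handle edge cases", {
  coh <- generate_cohort(cohort_profiles("HE"), c(HE = 15), seed = 14)
  cum <- cohort_cumulative(lapply(coh, segment_by_turns), n_max = 40)
  sl <- dplyr::filter(cum, parameter == "stride_length")
  prof <- convergence_profile(sl, "cum_mean")
  expect_equal(prof$r[prof$n == 40], 1)
  expect_equal(prof$n, 3:40)

  # a statistic constant in n (but varying across subjects) correlates
  # perfectly at every n
  flat <- tidyr::expand_grid(subject_id = letters[1:5], n = 3:10) |>
    dplyr::mutate(cum_mean = rep(c(1, 2, 3, 4, 5), each = 8))
  prof_flat <- convergence_profile(flat, "cum_mean")
  expect_equal(prof_flat$r, rep(1, 8))

  # no between-subject variance at N_max is undefined
  const <- tidyr::expand_grid(subject_id = letters[1:5], n = 3:10) |>
    dplyr::mutate(cum_mean = n)
  expect_error(convergence_profile(const, "cum_mean"), "Undefined")
  expect_error(convergence_profile(flat[1:20, ], "cum_mean"), "same n grid")
})

test_that("required stride count uses first crossing, optionally sustained", {
  prof <- structure(
    tibble::tibble(n = 3:9,
                   r = c(0.5, 0.7, 0.85, 0.79, 0.9, 0.95, 1.0)),
    statistic = "cum_cov", n_max = 9L,
    class = c("convergence_result", class(tibble::tibble()))
  )
  expect_equal(required_stride_count(prof, 0.8), 5L) # first crossing
  expect_equal(required_stride_count(prof, 0.8, sustained = TRUE), 7L)
  # profile above threshold from the start
  prof$r <- seq(0.85, 1, length.out = 7)
  expect_equal(required_stride_count(prof, 0.8), 3L)
  # final point is 1, so the result never exceeds N_max
  prof$r <- c(rep(0.1, 6), 1)
  expect_equal(required_stride_count(prof, 0.8), 9L)
})

test_that("cut-off classification is strictly greater-than", {
  expect_equal(classify_above_cutoff(c(2.7), 2.6)$n_above, 1)
  expect_equal(classify_above_cutoff(c(2.6), 2.6)$n_above, 0)
  expect_equal(classify_above_cutoff(numeric(0))$n_above, 0)
  res <- classify_above_cutoff(c(1, 2, 3, 4), 2.6)
  expect_equal(res$fraction, 0.5)
})

test_that("mean convergence R is non-decreasing in n without perturbation", {
  # averaged over seeded replicates of small unperturbed cohorts
  cfg <- generator_config(protocol_he(), periturn_delta_len_pct = 0,
                          periturn_delta_time_pct = 0)
  profs <- lapply(1:30, function(s) {
    coh <- generate_cohort(cohort_profiles("HE"), c(HE = 12),
                           seed = 7000 + s, config = cfg)
    cum <- cohort_cumulative(lapply(coh, segment_by_turns), n_max = 40)
    convergence_profile(
      dplyr::filter(cum, parameter == "stride_length"), "cum_mean"
    )$r
  })
  avg_r <- colMeans(do.call(rbind, profs))
  # allow tiny numerical wiggle between adjacent n
  expect_true(all(diff(avg_r) > -0.005))
  expect_gt(avg_r[1], 0.9)
})

test_that("tidiers return broom-shaped tibbles", {
  withr::with_seed(2, m <- matrix(rnorm(30, rep(rnorm(10, sd = 2), 3)), 10))
  res <- icc_two_way_random_single(m)
  td <- generics::tidy(res)
  expect_equal(td$term, c("subjects", "segments", "error"))
  expect_equal(td$df, c(9, 2, 18))
  gl <- generics::glance(res)
  expect_equal(gl$icc, res$icc)
  expect_equal(gl$band, res$band)

  coh <- generate_cohort(cohort_profiles("PD"), c(PD = 8), seed = 3)
  cum <- cohort_cumulative(lapply(coh, segment_by_turns), n_max = 40)
  prof <- convergence_profile(
    dplyr::filter(cum, parameter == "stride_time"), "cum_cov"
  )
  gl2 <- generics::glance(prof)
  expect_equal(gl2$n_max, 40L)
  expect_equal(gl2$n_required,
               required_stride_count(prof, 0.8))
})
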