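test_that("coefficient of variation matches hand computation", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50) # sd 1, mean 2
  # scale invariance
  x <- rexp(50) + 1
  expect_equal(coefficient_of_variation(x * 7.3),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(1), "fewer than 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "non-positive mean")
})

test_that("cumulative series reproduce whole-window statistics exactly", {
  withr::with_seed(1, x <- rnorm(40, 100, 2))
  cs <- cumulative_series(x, n_min = 3, n_max = 40)
  expect_equal(cs$n, 3:40)
  expect_equal(cs$cum_cov[cs$n == 40], coefficient_of_variation(x))
  expect_equal(cs$cum_mean[cs$n == 40], mean(x))
  expect_equal(cs$cum_mean[cs$n == 3], mean(x[1:3]))

  const <- cumulative_series(rep(4, 10))
  expect_true(all(const$cum_cov == 0))

  expect_error(cumulative_series(x[1:10], n_max = 40), "Need 40 values")
})

test_that("an extreme value makes the cumulative CoV jump then decay", {
  x <- rep(100, 40)
  x[20] <- 60 # one drastically short stride at position 20
  cs <- cumulative_series(x)
  expect_equal(cs$cum_cov[cs$n < 20], rep(0, sum(cs$n < 20)))
  expect_gt(cs$cum_cov[cs$n == 20], 5)
  after <- cs$cum_cov[cs$n >= 20]
  expect_true(all(diff(after) < 0)) # monotone decay once past the spike
})

test_that("per-segment statistics and their range are correct", {
  tr <- make_toy_trial(c(3, 3, 3), gap_s = 3,
                       stride_length = c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  seg <- segment_by_turns(tr)
  st <- per_segment_stats(seg, "stride_length")
  expect_equal(st$cov, rep(50, 3))
  expect_equal(attr(st, "cov_range"), 0)

  # short segments are skipped with a warning
  tr2 <- make_toy_trial(c(3, 2, 3), gap_s = 3,
                        stride_length = c(1, 2, 3, 9, 9, 2, 4, 6))
  expect_warning(st2 <- per_segment_stats(segment_by_turns(tr2),
                                          "stride_length"),
                 "Skipping")
  expect_equal(st2$segment_id, c(1L, 3L))
  expect_equal(attr(st2, "cov_range"), 50 - 50) # both segments CoV 50
  expect_error(
    suppressWarnings(per_segment_stats(segment_by_turns(
      make_toy_trial(c(2, 2), gap_s = 3)), "stride_length")),
    "No segment"
  )
})

test_that("peri-turn normalization expresses strides in % of reference", {
  he <- lapply(1:8, function(s) segment_by_turns(generate_trial(
    cohort_profile("HE"), generator_config(protocol_he()),
    subject_seed = 300 + s, subject_id = paste0("HE", s)
  )))
  pt <- extract_periturn_strides(he)
  ref <- periturn_reference(he, n_ref = 40)
  norm <- normalize_periturn(pt, ref)
  expect_true(all(c("rel_length_pct", "rel_time_pct") %in% names(norm)))
  # perturbed both sides by 1.2% length: pooled relative mean near 98.8%
  expect_lt(abs(mean(norm$rel_length_pct) - 98.8), 1)
  expect_lt(abs(mean(norm$rel_time_pct) - 101.4), 1)

  # a stride exactly at the reference maps to 100
  one <- tibble::tibble(subject_id = "a", group = "HE", turn_ordinal = 1L,
                        position = "before", stride_index = 1L,
                        stride_length_pct_stature = 80, stride_time_s = 1)
  refs <- tibble::tibble(subject_id = "a", ref_length_pct = 80,
                         ref_time_s = 1)
  expect_equal(normalize_periturn(one, refs)$rel_length_pct, 100)

  # empty set stays empty; bad reference raises
  expect_equal(nrow(normalize_periturn(pt[0, ], ref)), 0)
  expect_error(
    normalize_periturn(one, dplyr::mutate(refs, ref_length_pct = 0)),
    "positive"
  )
})

test_that("paired t statistic matches the closed form and t.test", {
  res <- paired_t_test(c(1, 2, 3))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)

  withr::with_seed(42, d <- rnorm(25, 0.3))
  res2 <- paired_t_test(d)
  oracle <- stats::t.test(d) # independent reference implementation
  expect_equal(res2$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res2$p.value, oracle$p.value, tolerance = 1e-12)

  # negating differences negates t, p unchanged
  res3 <- paired_t_test(-d)
  expect_equal(res3$statistic, -res2$statistic)
  expect_equal(res3$p.value, res2$p.value)

  expect_error(paired_t_test(rep(1, 5)), "zero variance")
  expect_error(paired_t_test(1), "at least 2")
})

test_that("peri-turn effect is detected by paired t-tests on normalized strides", {
  # synthetic movement-disorder cohorts, deltas 2.8/3.2%, >= 100 turns pooled
  rejections <- vapply(1:10, function(rep_seed) {
    coh <- generate_cohort(cohort_profile("MD"), c(MD = 26),
                           seed = 5000 + rep_seed,
                           config = generator_config(protocol_md()))
    segs <- lapply(coh, segment_by_turns)
    norm <- normalize_periturn(extract_periturn_strides(segs),
                               periturn_reference(segs))
    cmp <- periturn_comparison(norm)
    after_sl <- cmp[cmp$position == "after" &
                      cmp$parameter == "stride_length", ]
    after_sl$p.value < 0.01 & after_sl$rel_mean_pct < 100
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("density histograms integrate to unit mass with sample moments", {
  withr::with_seed(9, x <- rnorm(10000))
  h <- density_histogram(x, n_bins = 20)
  widths <- h$bins$edge_hi - h$bins$edge_lo
  expect_equal(sum(h$bins$density * widths), 1, tolerance = 1e-9)
  expect_lt(abs(h$mean - 0), 0.05)
  expect_lt(abs(h$sd - 1), 0.05)
  expect_equal(sum(h$bins$count), 10000)

  # degenerate sample: a single spike, sd 0
  spike <- density_histogram(rep(3, 5))
  expect_equal(nrow(spike$bins), 1)
  expect_equal(spike$sd, 0)
  expect_equal(sum(spike$bins$density *
                     (spike$bins$edge_hi - spike$bins$edge_lo)), 1)
  expect_error(density_histogram(1), "at least 2")
})
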