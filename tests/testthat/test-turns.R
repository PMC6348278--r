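test_that("the gap rule flags inter-onset intervals above the threshold", {
  # median stride time 1.0 s; a 3.0 s inter-onset interval exceeds
  # 1.5 x median, so exactly one gap is flagged between strides 4 and 5
  tr <- make_toy_trial(c(5, 5), gap_s = 2, stride_time = 1)
  turns <- detect_turn_gaps(tr, gap_factor = 1.5)
  expect_equal(nrow(turns), 1)
  expect_equal(turns$idx_before, 4L)
  expect_equal(turns$idx_after, 5L)
  expect_equal(turns$gap_start_s, 5)   # onset 4 + stride time 1
  expect_equal(turns$gap_end_s, 7)     # 5 strides + 2 s gap

  # no gaps in a single-segment trial; fewer than 2 records -> empty
  expect_equal(nrow(detect_turn_gaps(make_toy_trial(10))), 0)
  expect_equal(nrow(detect_turn_gaps(make_toy_trial(1))), 0)
})

test_that("detection is complete with zero false positives on clean trials", {
  # gap durations >= 2 s, stride times ~1 s: factor 1.5 finds every turn
  for (s in 1:25) {
    tr <- generate_trial(cohort_profile("HE"),
                         generator_config(protocol_he()), subject_seed = s)
    expect_equal(nrow(detect_turn_gaps(tr)), 2)
    tr <- generate_trial(cohort_profile("ATX"),
                         generator_config(protocol_md()),
                         subject_seed = 10000 + s)
    expect_equal(nrow(detect_turn_gaps(tr)), 4)
  }
})

test_that("QC flags missed turns and implausible short strides", {
  tr <- generate_trial(cohort_profile("HE"),
                       generator_config(protocol_he()), subject_seed = 4)
  qc <- qc_trial(tr)
  expect_false(qc$excluded)
  expect_equal(qc$n_turns_detected, 2L)

  inj <- inject_missed_turn(tr, 1)
  qc2 <- qc_trial(inj)
  expect_true(qc2$missed_turn_suspected)
  expect_true(qc2$excluded)

  # expected 4, detected 3: missed turn suspected
  three <- make_toy_trial(c(8, 8, 8, 8), gap_s = 3,
                          protocol = protocol_md())
  qc3 <- qc_trial(three)
  expect_equal(qc3$n_turns_detected, 3L)
  expect_true(qc3$missed_turn_suspected)
})

test_that("QC excludes exactly the contaminated trials in a cohort", {
  # 30-subject HE cohort with the missed-turn artifact injected into 5
  coh <- generate_cohort(cohort_profiles("HE"), c(HE = 30), seed = 6)
  contaminated <- names(coh)[c(3, 7, 11, 19, 28)]
  for (id in contaminated) coh[[id]] <- inject_missed_turn(coh[[id]], 1)
  qc <- dplyr::bind_rows(lapply(coh, qc_trial))
  expect_setequal(qc$subject_id[qc$excluded], contaminated)
  expect_equal(sum(qc$excluded), 5)
})

test_that("segmentation partitions the non-turning strides", {
  tr <- generate_trial(cohort_profile("ET"),
                       generator_config(protocol_md()), subject_seed = 9)
  seg <- segment_by_turns(tr)
  expect_equal(attr(seg, "n_segments"), 5L)
  expect_equal(sum(table(seg$segment_id)), 40)
  expect_equal(as.vector(table(seg$segment_id)), rep(8, 5))

  # 0 turns -> a single segment holding everything
  one <- segment_by_turns(make_toy_trial(10))
  expect_equal(unique(one$segment_id), 1L)

  # turning strides get no segment
  inj <- inject_missed_turn(tr, 1)
  seg2 <- segment_by_turns(inj, detect_turn_gaps(inj))
  expect_true(all(is.na(seg2$segment_id[seg2$periturn_tag == "turning"])))
  expect_true(all(!is.na(seg2$segment_id[seg2$periturn_tag != "turning"])))
})

test_that("generous excision removes the strides nearest each gap", {
  tr <- make_toy_trial(c(8, 8, 8, 8, 8), gap_s = 3,
                       protocol = protocol_md())
  seg <- segment_by_turns(tr)
  expect_equal(nrow(apply_extra_excision(seg, width = 0)), 40)
  w1 <- apply_extra_excision(seg, width = 1)
  expect_equal(nrow(w1), 32)   # 4 turns x 2 sides x 1 stride removed
  # trial boundary strides survive; gap-adjacent ones are gone
  expect_true(0 %in% w1$stride_index)
  expect_true(39 %in% w1$stride_index)
  expect_false(7 %in% w1$stride_index)
  expect_false(8 %in% w1$stride_index)
  expect_false(is.unsorted(w1$onset_s))

  # monotone in width, robust to segments shorter than the width
  counts <- vapply(0:4, function(w)
    nrow(apply_extra_excision(seg, width = w)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  tiny <- segment_by_turns(make_toy_trial(c(4, 1, 4), gap_s = 3))
  w_tiny <- apply_extra_excision(tiny, width = 1)
  expect_false(2L %in% w_tiny$segment_id) # middle singleton fully removed
  expect_equal(nrow(w_tiny), 6)
})

test_that("peri-turn extraction pools the strides flanking used turns", {
  md <- lapply(1:5, function(s) segment_by_turns(
    generate_trial(cohort_profile("MD"), generator_config(protocol_md()),
                   subject_seed = 100 + s, subject_id = paste0("MD", s))
  ))
  pooled <- extract_periturn_strides(md)
  expect_equal(nrow(pooled), 5 * 4 * 2)
  expect_equal(sum(pooled$position == "before"), 20)

  # the HE protocol caps usage at the first two turns
  he <- segment_by_turns(generate_trial(
    cohort_profile("HE"), generator_config(protocol_he()), subject_seed = 1
  ))
  expect_equal(nrow(extract_periturn_strides(list(he))), 4)
  expect_equal(sort(unique(extract_periturn_strides(list(he))$turn_ordinal)),
               c(1L, 2L))

  # counting identity: one before + one after per used turn
  turns_used <- nrow(attr(he, "turns"))
  expect_equal(nrow(extract_periturn_strides(he)), 2 * min(turns_used, 2))
})
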