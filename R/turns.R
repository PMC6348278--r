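#' Detect turns as gaps in the stride time series
#'
#' After turn excision by the recording software, a 180-degree turn leaves
#' no strides behind — only a hole in the timestamps. A turn is therefore
#' flagged wherever the interval between consecutive stride onsets exceeds
#' `gap_factor` times the trial's median stride time; referencing the
#' subject's own median makes the rule robust to slow and fast walkers
#' alike. The reported gap runs from the end of the last stride before it
#' (`onset_s + stride_time_s`) to the onset of the first stride after it.
#'
#' @param trial A [gait_trial()].
#' @param gap_factor Multiplier on the median stride time above which an
#'   inter-onset interval counts as a gap (default 1.5).
#' @return A tibble of turn events ordered by time, with columns `turn_id`,
#'   `gap_start_s`, `gap_end_s`, `idx_before`, `idx_after` (0-based record
#'   indices flanking the gap). Zero rows when the trial has fewer than two
#'   records or no gap.
#' @examples
#' tr <- generate_trial(cohort_profile("PD"), generator_config(protocol_md()),
#'                      subject_seed = 7)
#' detect_turn_gaps(tr)
#' @export
detect_turn_gaps <- function(trial, gap_factor = 1.5) {
  stopifnot(inherits(trial, "gait_trial"))
  n <- nrow(trial)
  empty <- tibble(
    turn_id = integer(), gap_start_s = numeric(), gap_end_s = numeric(),
    idx_before = integer(), idx_after = integer()
  )
  if (n < 2) return(empty)
  ioi <- diff(trial$onset_s)
  threshold <- gap_factor * stats::median(trial$stride_time_s)
  hit <- which(ioi > threshold)
  if (length(hit) == 0) return(empty)
  tibble(
    turn_id = seq_along(hit),
    gap_start_s = trial$onset_s[hit] + trial$stride_time_s[hit],
    gap_end_s = trial$onset_s[hit + 1L],
    idx_before = trial$stride_index[hit],
    idx_after = trial$stride_index[hit + 1L]
  )
}

#' Quality-control a trial for non-detected turns
#'
#' A trial whose export contains fewer timestamp gaps than the protocol's
#' turn count has most likely suffered a non-detected turn, in which case
#' the very short turning strides contaminate the stride series and inflate
#' its coefficient of variation. Two automated checks capture the visual
#' criteria used in practice: a `missed_turn_suspected` flag when fewer
#' gaps than expected are found, and an `implausible_short_strides` flag
#' when any stride not adjacent to a gap is shorter than
#' `short_stride_frac` of the trial's median stride length. A trial raising
#' either flag is marked `excluded` and should be dropped from downstream
#' statistics rather than repaired.
#'
#' @param trial A [gait_trial()].
#' @param turns Turn events from [detect_turn_gaps()].
#' @param protocol A [protocol_spec()]; defaults to the trial's own.
#' @param short_stride_frac Fraction of the median stride length below
#'   which a non-gap-adjacent stride is implausibly short (default 0.5).
#' @param min_strides Minimum stride count; shortfalls raise the
#'   `too_few_strides` flag (reported, but not by itself excluding).
#' @return A one-row tibble of class `qc_report`: `subject_id`,
#'   `n_turns_detected`, `n_turns_expected`, logical flags
#'   `missed_turn_suspected`, `implausible_short_strides`,
#'   `too_few_strides`, and `excluded`.
#' @export
qc_trial <- function(trial, turns = detect_turn_gaps(trial),
                     protocol = trial_protocol(trial),
                     short_stride_frac = 0.5, min_strides = 40L) {
  stopifnot(inherits(trial, "gait_trial"), inherits(protocol, "protocol_spec"))
  n_detected <- nrow(turns)
  n_expected <- protocol$expected_turns
  missed <- n_detected < n_expected

  adjacent <- unique(c(turns$idx_before, turns$idx_after))
  non_adjacent <- !(trial$stride_index %in% adjacent)
  med_sl <- stats::median(trial$stride_length_pct_stature)
  implausible <- any(
    trial$stride_length_pct_stature[non_adjacent] < short_stride_frac * med_sl
  )

  out <- tibble(
    subject_id = trial$subject_id[[1]],
    n_turns_detected = n_detected,
    n_turns_expected = n_expected,
    missed_turn_suspected = missed,
    implausible_short_strides = implausible,
    too_few_strides = nrow(trial) < min_strides,
    excluded = missed || implausible
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Split a trial into straight-walking segments
#'
#' Assigns every stride to the straight segment it belongs to: segment 1
#' before the first detected gap, segment 2 between the first and second
#' gap, and so on. The number of segments always equals the number of
#' detected turns plus one (a segment can be empty if a gap abuts the
#' trial boundary, which draws a warning). Strides tagged `"turning"` —
#' present only when a missed-turn artifact contaminates the export — are
#' assigned no segment (`NA`).
#'
#' @param trial A [gait_trial()].
#' @param turns Turn events from [detect_turn_gaps()].
#' @return The trial tibble with an added integer `segment_id` column, of
#'   class `segmented_trial`, carrying the turn events in the `turns`
#'   attribute.
#' @examples
#' tr <- generate_trial(cohort_profile("HE"), generator_config(protocol_he()),
#'                      subject_seed = 3)
#' seg <- segment_by_turns(tr)
#' table(seg$segment_id)
#' @export
segment_by_turns <- function(trial, turns = detect_turn_gaps(trial)) {
  stopifnot(inherits(trial, "gait_trial"))
  n_segments <- nrow(turns) + 1L
  seg_id <- findInterval(trial$onset_s, turns$gap_end_s) + 1L
  seg_id[trial$periturn_tag == "turning"] <- NA_integer_
  out <- mutate(as_tibble(trial), segment_id = as.integer(seg_id))
  present <- unique(stats::na.omit(seg_id))
  if (length(present) < n_segments) {
    warn(sprintf("%d of %d segments contain no strides.",
                 n_segments - length(present), n_segments))
  }
  structure(
    out,
    protocol = trial_protocol(trial),
    turns = turns,
    n_segments = n_segments,
    class = c("segmented_trial", class(tibble()))
  )
}

#' @export
print.segmented_trial <- function(x, ...) {
  cat(sprintf("<segmented_trial> %d strides, %d segments, %d turn(s)\n",
              nrow(x), attr(x, "n_segments", exact = TRUE),
              nrow(attr(x, "turns", exact = TRUE))))
  NextMethod()
}

#' Apply generous turn excision
#'
#' Automated turn excision may clip turns too tightly, leaving perturbed
#' strides — spatially shorter, temporally longer — directly adjacent to
#' each gap. A more generous segmentation removes the `width` strides
#' nearest each gap on both sides (fewer when a segment is shorter than
#' requested), on top of the turn excision already encoded by the gaps.
#' With `width = 0` the output is simply every segmented (non-turning)
#' stride. A trial of 40 strides and 4 turns loses 8 strides at
#' `width = 1`, leaving the 32-stride analysis window the generous mode is
#' paired with.
#'
#' @param seg A [segment_by_turns()] result.
#' @param width Number of extra strides removed on each side of every gap.
#' @return A tibble of the surviving strides in onset order (columns of the
#'   trial plus `segment_id`). Stride indices keep their original values.
#' @export
apply_extra_excision <- function(seg, width = 1L) {
  stopifnot(inherits(seg, "segmented_trial"), width >= 0)
  width <- as.integer(width)
  n_segments <- attr(seg, "n_segments", exact = TRUE)
  out <- filter(as_tibble(seg), !is.na(.data$segment_id))
  if (width == 0L || n_segments == 1L) return(out)
  out <- out |>
    group_by(.data$segment_id) |>
    filter(
      # drop first `width` rows unless this is the opening segment,
      # and last `width` rows unless it is the closing one
      (row_number() > width | .data$segment_id == 1L) &
        (row_number() <= n() - width | .data$segment_id == n_segments)
    ) |>
    ungroup()
  out
}

#' Extract strides directly before and after turns
#'
#' Pools, across a cohort of segmented trials, the single strides
#' immediately flanking each used turn gap. The number of turns used per
#' trial is capped at the protocol's `max_turns_used` (all four turns in
#' the movement-disorder protocol; only the first two in the
#' healthy-elderly protocol, the minimum every participant performed). A
#' gap at a trial boundary contributes only the neighbor it has.
#'
#' @param cohort A list of [segment_by_turns()] results (QC-excluded
#'   trials should be removed by the caller), or a single one.
#' @return A tibble with one row per contributed peri-turn stride:
#'   `subject_id`, `group`, `turn_ordinal`, `position` (`"before"` /
#'   `"after"`), `stride_index`, `stride_length_pct_stature`,
#'   `stride_time_s`.
#' @examples
#' coh <- generate_cohort(cohort_profiles("HE"), c(HE = 4), seed = 9)
#' segs <- lapply(coh, segment_by_turns)
#' nrow(extract_periturn_strides(segs)) # 4 subjects x 2 turns x 2 sides
#' @export
extract_periturn_strides <- function(cohort) {
  if (inherits(cohort, "segmented_trial")) cohort <- list(cohort)
  rows <- purrr::map(cohort, function(seg) {
    turns <- attr(seg, "turns", exact = TRUE)
    proto <- attr(seg, "protocol", exact = TRUE)
    n_use <- min(nrow(turns), proto$max_turns_used)
    if (n_use == 0) return(NULL)
    used <- turns[seq_len(n_use), ]
    tbl <- as_tibble(seg)
    one_side <- function(idx, ordinal, position) {
      hit <- match(idx, tbl$stride_index)
      if (is.na(hit)) return(NULL)
      tibble(
        subject_id = tbl$subject_id[[hit]],
        group = tbl$group[[hit]],
        turn_ordinal = ordinal,
        position = position,
        stride_index = tbl$stride_index[[hit]],
        stride_length_pct_stature = tbl$stride_length_pct_stature[[hit]],
        stride_time_s = tbl$stride_time_s[[hit]]
      )
    }
    bind_rows(
      purrr::map2(used$idx_before, used$turn_id, one_side,
                  position = "before"),
      purrr::map2(used$idx_after, used$turn_id, one_side,
                  position = "after")
    )
  })
  bind_rows(rows)
}
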