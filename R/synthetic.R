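#' Generative parameters for one cohort
#'
#' A cohort profile holds the group-level statistics a synthetic cohort is
#' drawn from: the between-subject distribution of mean stride length
#' (percent stature) and mean stride time (seconds), and the within-subject
#' coefficients of variation that set stride-to-stride spread.
#'
#' Calling `cohort_profile()` with just a group label returns the built-in
#' profile for that cohort: healthy elderly (`"HE"`), pooled movement
#' disorders (`"MD"`), cerebellar ataxia (`"ATX"`), essential tremor
#' (`"ET"`) or Parkinson's disease (`"PD"`). The built-ins reproduce
#' published group means, between-subject SDs and within-subject CoVs for
#' these cohorts, e.g. HE stride length 86.13 +/- 4.83 % stature with
#' CoV 1.99%, stride time 1.02 +/- 0.06 s with CoV 2.10%.
#'
#' @param group Cohort label.
#' @param mean_sl_pct,sd_sl_between Mean and between-subject SD of mean
#'   stride length, in percent stature.
#' @param mean_st_s,sd_st_between Mean and between-subject SD of mean
#'   stride time, in seconds.
#' @param cov_sl_pct,cov_st_pct Within-subject CoV of stride length and
#'   stride time, in percent.
#' @return A `cohort_profile` object (named list).
#' @examples
#' cohort_profile("HE")
#' cohort_profile("HE", cov_sl_pct = 0, sd_sl_between = 0) # noiseless lengths
#' @export
cohort_profile <- function(group,
                           mean_sl_pct = NULL, sd_sl_between = NULL,
                           cov_sl_pct = NULL,
                           mean_st_s = NULL, sd_st_between = NULL,
                           cov_st_pct = NULL) {
  defaults <- .profile_defaults[[group]]
  if (is.null(defaults) &&
      (is.null(mean_sl_pct) || is.null(mean_st_s))) {
    abort(paste0(
      "No built-in profile for group '", group,
      "'; supply means, SDs and CoVs explicitly."
    ))
  }
  pick <- function(value, field) {
    value %||% defaults[[field]]
  }
  out <- list(
    group = as.character(group),
    mean_sl_pct = pick(mean_sl_pct, "mean_sl_pct"),
    sd_sl_between = pick(sd_sl_between, "sd_sl_between"),
    cov_sl_pct = pick(cov_sl_pct, "cov_sl_pct"),
    mean_st_s = pick(mean_st_s, "mean_st_s"),
    sd_st_between = pick(sd_st_between, "sd_st_between"),
    cov_st_pct = pick(cov_st_pct, "cov_st_pct")
  )
  if (out$mean_sl_pct <= 0 || out$mean_st_s <= 0) {
    abort("Profile means must be positive.")
  }
  if (min(out$sd_sl_between, out$sd_st_between,
          out$cov_sl_pct, out$cov_st_pct) < 0) {
    abort("Profile SDs and CoVs must be non-negative.")
  }
  structure(out, class = "cohort_profile")
}

.profile_defaults <- list(
  HE  = list(mean_sl_pct = 86.13, sd_sl_between = 4.83, cov_sl_pct = 1.99,
             mean_st_s = 1.02, sd_st_between = 0.06, cov_st_pct = 2.10),
  MD  = list(mean_sl_pct = 76.99, sd_sl_between = 7.04, cov_sl_pct = 3.41,
             mean_st_s = 1.04, sd_st_between = 0.11, cov_st_pct = 3.54),
  ATX = list(mean_sl_pct = 76.06, sd_sl_between = 7.55, cov_sl_pct = 5.61,
             mean_st_s = 1.12, sd_st_between = 0.20, cov_st_pct = 5.65),
  ET  = list(mean_sl_pct = 78.50, sd_sl_between = 6.66, cov_sl_pct = 2.74,
             mean_st_s = 1.02, sd_st_between = 0.07, cov_st_pct = 3.14),
  PD  = list(mean_sl_pct = 76.02, sd_sl_between = 7.45, cov_sl_pct = 2.81,
             mean_st_s = 0.99, sd_st_between = 0.05, cov_st_pct = 2.70)
)

#' Built-in cohort profiles
#'
#' @param groups Which groups to return (default: the four analyzed
#'   cohorts).
#' @return A named list of [cohort_profile()] objects.
#' @export
cohort_profiles <- function(groups = c("HE", "ATX", "ET", "PD")) {
  out <- lapply(groups, cohort_profile)
  names(out) <- groups
  out
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf(
    "<cohort_profile %s> SL %.2f +/- %.2f %%stature (CoV %.2f%%), ST %.3f +/- %.3f s (CoV %.2f%%)\n",
    x$group, x$mean_sl_pct, x$sd_sl_between, x$cov_sl_pct,
    x$mean_st_s, x$sd_st_between, x$cov_st_pct
  ))
  invisible(x)
}

#' Configure the synthetic trial generator
#'
#' The configuration fixes the mechanics of one simulated walk: how many
#' strides each straight segment contains, how long the timestamp gap left
#' by an excised turn lasts, and how strides adjacent to turns are
#' perturbed.
#'
#' Peri-turn defaults depend on the protocol: for the movement-disorder
#' walk (4 turns around tape lines) strides directly after turns are 2.8%
#' shorter and 3.2% longer in time than the subject's average; for the
#' healthy-elderly walk (turns around pylons) strides both before and
#' after turns are perturbed by 1.2% (length) and 1.4% (time). Turn gap
#' duration defaults to uniform on 2-5 s, comfortably above any plausible
#' stride time so a real turn is always separable from a long stride.
#'
#' @param protocol A [protocol_spec()].
#' @param strides_per_segment Strides per straight segment. Defaults to 8
#'   for a 10 m segment and 14 for a 20 m segment (roughly 1.3 m strides),
#'   so both preset protocols yield at least 40 strides per trial.
#' @param turn_duration_range Length-2 numeric, uniform range (s) of the
#'   timestamp gap an excised turn leaves.
#' @param periturn_delta_len_pct Percent shortening of perturbed peri-turn
#'   stride lengths.
#' @param periturn_delta_time_pct Percent lengthening of perturbed
#'   peri-turn stride times.
#' @param periturn_scope `"after_only"` or `"before_and_after"`.
#' @return A `generator_config` object.
#' @export
generator_config <- function(protocol = protocol_md(),
                             strides_per_segment = NULL,
                             turn_duration_range = c(2, 5),
                             periturn_delta_len_pct = NULL,
                             periturn_delta_time_pct = NULL,
                             periturn_scope = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  he_like <- protocol$segment_length_m >= 15
  strides_per_segment <- strides_per_segment %||% if (he_like) 14L else 8L
  periturn_scope <- periturn_scope %||%
    if (he_like) "before_and_after" else "after_only"
  periturn_scope <- match.arg(periturn_scope,
                              c("after_only", "before_and_after"))
  periturn_delta_len_pct <- periturn_delta_len_pct %||%
    if (he_like) 1.2 else 2.8
  periturn_delta_time_pct <- periturn_delta_time_pct %||%
    if (he_like) 1.4 else 3.2
  if (length(turn_duration_range) != 2 || any(turn_duration_range <= 0) ||
      diff(turn_duration_range) < 0) {
    abort("`turn_duration_range` must be an increasing positive pair.")
  }
  if (periturn_delta_len_pct < 0 || periturn_delta_time_pct < 0) {
    abort("Peri-turn deltas must be >= 0.")
  }
  structure(
    list(
      protocol = protocol,
      strides_per_segment = as.integer(strides_per_segment),
      turn_duration_range = as.numeric(turn_duration_range),
      periturn_delta_len_pct = periturn_delta_len_pct,
      periturn_delta_time_pct = periturn_delta_time_pct,
      periturn_scope = periturn_scope
    ),
    class = "generator_config"
  )
}

# Gaussian draws with a positivity guard: values below 10% of the mean are
# redrawn (needed only at extreme CoVs), with a warning.
draw_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  floor_val <- 0.1 * mean
  bad <- x < floor_val
  if (any(bad)) {
    warn("Resampling stride values below 10% of the subject mean.")
    for (i in seq_len(50)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < floor_val
      if (!any(bad)) break
    }
    x[bad] <- floor_val
  }
  x
}

#' Simulate one gait trial
#'
#' Draws a subject's mean stride length and stride time from the cohort's
#' between-subject distributions, then draws each stride independently from
#' a normal distribution around the subject mean with SD equal to
#' `mean x CoV/100`. Stride onsets are the cumulative sums of stride times;
#' between consecutive straight segments a timestamp gap (the excised turn)
#' is inserted. Strides adjacent to a gap are tagged `before_turn` /
#' `after_turn` and perturbed according to the configuration's peri-turn
#' scope and deltas. Output is fully determined by `subject_seed`.
#'
#' @param profile A [cohort_profile()].
#' @param config A [generator_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @param subject_id Label for the subject (defaults to
#'   `"<group>_s<seed>"`).
#' @return A [gait_trial()].
#' @examples
#' tr <- generate_trial(cohort_profile("ATX"), generator_config(protocol_md()),
#'                      subject_seed = 42)
#' nrow(tr)                         # 5 segments x 8 strides
#' nrow(detect_turn_gaps(tr))       # 4 turns
#' @export
generate_trial <- function(profile, config, subject_seed,
                           subject_id = NULL) {
  stopifnot(inherits(profile, "cohort_profile"),
            inherits(config, "generator_config"))
  proto <- config$protocol
  n_seg <- proto$n_segments
  k <- config$strides_per_segment
  n <- n_seg * k
  subject_id <- subject_id %||%
    sprintf("%s_s%d", profile$group, as.integer(subject_seed))

  withr::with_seed(as.integer(subject_seed), {
    subj_sl <- draw_positive(1, profile$mean_sl_pct, profile$sd_sl_between)
    subj_st <- draw_positive(1, profile$mean_st_s, profile$sd_st_between)
    sl <- draw_positive(n, subj_sl, subj_sl * profile$cov_sl_pct / 100)
    st <- draw_positive(n, subj_st, subj_st * profile$cov_st_pct / 100)
    gaps <- stats::runif(n_seg - 1,
                         config$turn_duration_range[1],
                         config$turn_duration_range[2])

    # peri-turn strides: last of segments 1..n_seg-1, first of 2..n_seg
    tag <- rep("none", n)
    before_idx <- if (n_seg > 1) seq_len(n_seg - 1) * k else integer()
    after_idx <- if (n_seg > 1) seq_len(n_seg - 1) * k + 1L else integer()
    tag[before_idx] <- "before_turn"
    tag[after_idx] <- "after_turn"

    perturb <- after_idx
    if (config$periturn_scope == "before_and_after") {
      perturb <- c(before_idx, after_idx)
    }
    sl[perturb] <- sl[perturb] * (1 - config$periturn_delta_len_pct / 100)
    st[perturb] <- st[perturb] * (1 + config$periturn_delta_time_pct / 100)

    onset <- cumsum(c(0, st[-n]))
    if (n_seg > 1) {
      seg_of <- rep(seq_len(n_seg), each = k)
      onset <- onset + c(0, cumsum(gaps))[seg_of]
    }

    gait_trial(
      tibble(
        stride_index = seq_len(n) - 1L,
        onset_s = onset,
        stride_length_pct_stature = sl,
        stride_time_s = st,
        periturn_tag = tag
      ),
      subject_id = subject_id,
      group = profile$group,
      protocol = proto
    )
  })
}

#' Simulate a multi-group cohort
#'
#' Generates `n_per_group[[g]]` trials for each profile `g`, with
#' per-subject seeds derived reproducibly from the master seed: the same
#' `(profiles, n_per_group, seed)` always yields the identical cohort.
#' Unless an explicit configuration is supplied, HE subjects walk the
#' healthy-elderly protocol (3 x 20 m) and every other group the
#' movement-disorder protocol (5 x 10 m).
#'
#' @param profiles A named list of [cohort_profile()] objects (e.g.
#'   [cohort_profiles()]), or a single profile.
#' @param n_per_group Named integer vector of subjects per group; groups
#'   with 0 subjects are allowed and contribute nothing.
#' @param seed Master integer seed.
#' @param config A [generator_config()] applied to every group, or `NULL`
#'   to pick the protocol-appropriate default per group.
#' @return A named list of [gait_trial()] objects.
#' @examples
#' coh <- generate_cohort(cohort_profiles("HE"), c(HE = 5), seed = 1)
#' length(coh)
#' @export
generate_cohort <- function(profiles, n_per_group, seed, config = NULL) {
  if (inherits(profiles, "cohort_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$group)
  }
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(profiles))) {
    abort("`n_per_group` must be named by groups present in `profiles`.")
  }
  total <- sum(n_per_group)
  subject_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, total)
  )
  out <- list()
  pos <- 0L
  for (g in groups) {
    n_g <- n_per_group[[g]]
    if (n_g == 0) next
    cfg <- config %||% generator_config(
      if (identical(g, "HE")) protocol_he() else protocol_md()
    )
    for (i in seq_len(n_g)) {
      pos <- pos + 1L
      id <- sprintf("%s%03d", g, i)
      out[[id]] <- generate_trial(profiles[[g]], cfg,
                                  subject_seed = subject_seeds[pos],
                                  subject_id = id)
    }
  }
  out
}

#' Inject a missed-turn artifact into a trial
#'
#' Emulates the failure mode where a turn is not segmented by the export
#' software: instead of a timestamp gap, the export contains the turning
#' strides themselves — drastically shorter steps that inflate the trial's
#' coefficient of variation beyond the physiological range. The chosen gap
#' is replaced by `n_turn_strides` records tagged `"turning"`, each with
#' length `shrink_factor` times the subject's mean stride length and with
#' stride times that exactly fill the former gap. With `n_turn_strides = 0`
#' the gap is simply closed (later onsets shift earlier), leaving the
#' strides contiguous.
#'
#' @param trial A [gait_trial()] containing at least `turn_ordinal` gaps.
#' @param turn_ordinal Which detected gap to overwrite (1-based).
#' @param n_turn_strides How many turning strides to insert.
#' @param shrink_factor Fraction of the subject's mean stride length the
#'   turning strides measure; must lie in (0, 1).
#' @param gap_factor Gap-detection threshold used to locate the existing
#'   gaps (see [detect_turn_gaps()]).
#' @return A new [gait_trial()] with one fewer detectable gap.
#' @export
inject_missed_turn <- function(trial, turn_ordinal, n_turn_strides = 4L,
                               shrink_factor = 0.4, gap_factor = 1.5) {
  stopifnot(inherits(trial, "gait_trial"))
  if (shrink_factor <= 0 || shrink_factor >= 1) {
    abort("`shrink_factor` must be in (0, 1).")
  }
  turns <- detect_turn_gaps(trial, gap_factor = gap_factor)
  if (turn_ordinal < 1 || turn_ordinal > nrow(turns)) {
    abort(sprintf("`turn_ordinal` %d out of range: trial has %d gap(s).",
                  turn_ordinal, nrow(turns)))
  }
  ev <- turns[turn_ordinal, ]
  gap_dur <- ev$gap_end_s - ev$gap_start_s
  tbl <- as_tibble(trial)
  i_before <- ev$idx_before + 1L # row number of the stride before the gap

  if (n_turn_strides == 0) {
    tbl$onset_s[(i_before + 1L):nrow(tbl)] <-
      tbl$onset_s[(i_before + 1L):nrow(tbl)] - gap_dur
    new_records <- tbl
  } else {
    mean_sl <- mean(tbl$stride_length_pct_stature[tbl$periturn_tag != "turning"])
    t_each <- gap_dur / n_turn_strides
    turning <- tibble(
      subject_id = tbl$subject_id[[1]],
      group = tbl$group[[1]],
      stride_index = NA_integer_,
      onset_s = ev$gap_start_s + (seq_len(n_turn_strides) - 1L) * t_each,
      stride_length_pct_stature = shrink_factor * mean_sl,
      stride_time_s = t_each,
      periturn_tag = "turning"
    )
    new_records <- bind_rows(
      tbl[seq_len(i_before), ],
      turning,
      tbl[(i_before + 1L):nrow(tbl), ]
    )
  }
  gait_trial(
    new_records[, c("onset_s", "stride_length_pct_stature",
                    "stride_time_s", "periturn_tag")],
    subject_id = tbl$subject_id[[1]],
    group = tbl$group[[1]],
    protocol = trial_protocol(trial),
    stature_m = attr(trial, "stature_m", exact = TRUE)
  )
}
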