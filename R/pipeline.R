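#' Analysis configuration
#'
#' Bundles the fixed constants of the stride-count analysis. The default
#' excision width 0 analyzes the export as delivered (standard turn
#' excision) over a 3-40 stride window; width 1 is the generous mode that
#' drops one extra stride on each side of every turn and, having fewer
#' strides to work with, references a 3-32 window instead.
#'
#' @param excision_width Extra strides removed per side of each turn
#'   (0 = standard excision, 1 = generous).
#' @param gap_factor Turn-detection threshold (see [detect_turn_gaps()]).
#' @param short_stride_frac QC threshold (see [qc_trial()]).
#' @param n_min,n_max Cumulative window bounds; `n_max` defaults to 40 for
#'   width 0 and 32 otherwise.
#' @param criterion_r Reliability criterion on Pearson R (default 0.8).
#' @param cov_cutoff_pct Cut-off for increased CoV, percent (default 2.6).
#' @param min_strides Minimum stride count per trial (default 40).
#' @param sustained Use sustained- instead of first-crossing for the
#'   required stride count.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(excision_width = 0L, gap_factor = 1.5,
                            short_stride_frac = 0.5, n_min = 3L,
                            n_max = NULL, criterion_r = 0.8,
                            cov_cutoff_pct = 2.6, min_strides = 40L,
                            sustained = FALSE) {
  excision_width <- as.integer(excision_width)
  if (excision_width < 0) abort("`excision_width` must be >= 0.")
  n_max <- as.integer(n_max %||% if (excision_width == 0L) 40L else 32L)
  if (n_min >= n_max) abort("`n_min` must be below `n_max`.")
  if (criterion_r <= 0 || criterion_r >= 1) {
    abort("`criterion_r` must lie in (0, 1).")
  }
  structure(
    list(
      excision_width = excision_width, gap_factor = gap_factor,
      short_stride_frac = short_stride_frac,
      n_min = as.integer(n_min), n_max = n_max,
      criterion_r = criterion_r, cov_cutoff_pct = cov_cutoff_pct,
      min_strides = as.integer(min_strides), sustained = sustained
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    "<analysis_config> width %d, window %d-%d, gap factor %.2f, R > %.2f, CoV cut-off %.1f%%\n",
    x$excision_width, x$n_min, x$n_max, x$gap_factor, x$criterion_r,
    x$cov_cutoff_pct
  ))
  invisible(x)
}

#' Per-subject stride statistics
#'
#' Mean and CoV of stride length and stride time over each subject's first
#' `n_max` analyzed (post-excision) strides. Trials with fewer analyzed
#' strides than `n_max` are dropped with a warning.
#'
#' @param cohort A list of [segment_by_turns()] results.
#' @param width Extra excision width.
#' @param n_max Number of leading analyzed strides used.
#' @return A tibble: `subject_id`, `group`, `n_strides`, `mean_sl`,
#'   `mean_st`, `cov_sl`, `cov_st`.
#' @export
subject_stats <- function(cohort, width = 0L, n_max = 40L) {
  if (inherits(cohort, "segmented_trial")) cohort <- list(cohort)
  rows <- purrr::map(cohort, function(seg) {
    strides <- apply_extra_excision(seg, width = width)
    if (nrow(strides) < n_max) {
      warn(sprintf("Trial %s has %d analyzed strides (< %d); dropped.",
                   strides$subject_id[1] %||% "?", nrow(strides), n_max))
      return(NULL)
    }
    use <- utils::head(strides, n_max)
    tibble(
      subject_id = use$subject_id[[1]],
      group = use$group[[1]],
      n_strides = nrow(use),
      mean_sl = mean(use$stride_length_pct_stature),
      mean_st = mean(use$stride_time_s),
      cov_sl = coefficient_of_variation(use$stride_length_pct_stature),
      cov_st = coefficient_of_variation(use$stride_time_s)
    )
  })
  bind_rows(rows)
}

#' Group summary of stride parameters
#'
#' Group-level mean and SD of the subject-level stride length, stride
#' time, and their CoVs — the cohort-description table of the analysis.
#' With a single subject in a group the SDs are `NA`.
#'
#' @param trials A list of [gait_trial()] or [segment_by_turns()] objects
#'   (the analyzed cohort, QC-excluded trials removed).
#' @param width,n_max Passed to [subject_stats()].
#' @return A tibble, one row per group: `group`, `n`, then `mean`/`sd`
#'   pairs for `sl`, `st`, `cov_sl`, `cov_st`.
#' @export
summarize_cohort <- function(trials, width = 0L, n_max = 40L) {
  segs <- purrr::map(trials, function(x) {
    if (inherits(x, "segmented_trial")) x else segment_by_turns(x)
  })
  stats_tbl <- subject_stats(segs, width = width, n_max = n_max)
  if (nrow(stats_tbl) == 0) abort("No analyzable trials.")
  stats_tbl |>
    group_by(group = .data$group) |>
    summarise(
      n = n(),
      # SDs first: summarise evaluates sequentially and the mean_* outputs
      # shadow the input columns of the same name
      sd_sl = stats::sd(.data$mean_sl), mean_sl = mean(.data$mean_sl),
      sd_st = stats::sd(.data$mean_st), mean_st = mean(.data$mean_st),
      mean_cov_sl = mean(.data$cov_sl), sd_cov_sl = stats::sd(.data$cov_sl),
      mean_cov_st = mean(.data$cov_st), sd_cov_st = stats::sd(.data$cov_st),
      .groups = "drop"
    ) |>
    select("group", "n", "mean_sl", "sd_sl", "mean_st", "sd_st",
           "mean_cov_sl", "sd_cov_sl", "mean_cov_st", "sd_cov_st")
}

#' Run the full stride-count analysis pipeline
#'
#' Sequences the whole analysis on a cohort of trials: turn detection, QC
#' for non-detected turns (excluded trials are dropped, never repaired),
#' segmentation and (optionally generous) turn excision, per-subject and
#' group descriptive statistics, per-segment statistics with ICC(2,1)
#' across segments, cumulative mean/CoV series, convergence profiles
#' against the final-stride value, and the required stride count per
#' group, parameter and statistic. Deterministic given its inputs.
#'
#' @param trials A named list of [gait_trial()] objects, or the path of a
#'   cohort manifest CSV (see [read_cohort_manifest()]).
#' @param config An [analysis_config()].
#' @return A `gait_report`: list with elements `config`, `qc`,
#'   `subject_stats`, `group_summary`, `segment_stats`, `icc`,
#'   `cumulative`, `convergence`, `n_required`, `periturn`, and `log`
#'   (character vector of stage-level counts).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_profiles(c("HE", "PD")),
#'                        c(HE = 20, PD = 8), seed = 11)
#' rep <- run_pipeline(coh, analysis_config())
#' rep$n_required
#' }
#' @export
run_pipeline <- function(trials, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(trials)) trials <- read_cohort_manifest(trials)
  log <- c(
    sprintf("config: width=%d window=%d-%d gap_factor=%.2f criterion_r=%.2f cov_cutoff=%.2f",
            config$excision_width, config$n_min, config$n_max,
            config$gap_factor, config$criterion_r, config$cov_cutoff_pct),
    sprintf("trials in: %d", length(trials))
  )

  # QC: detect gaps, flag and drop trials with suspected missed turns
  turns_by_trial <- purrr::map(trials, detect_turn_gaps,
                               gap_factor = config$gap_factor)
  qc <- purrr::map2(trials, turns_by_trial, function(tr, tu) {
    qc_trial(tr, tu, short_stride_frac = config$short_stride_frac,
             min_strides = config$min_strides)
  }) |> bind_rows()
  keep <- !qc$excluded
  log <- c(log, sprintf("QC-excluded: %d of %d", sum(!keep), length(keep)))
  if (!any(keep)) abort("All trials were QC-excluded; nothing to analyze.")
  analyzed <- trials[keep]
  segs <- purrr::map2(analyzed, turns_by_trial[keep], segment_by_turns)
  log <- c(log, sprintf("analyzed: %d", length(analyzed)))

  stats_tbl <- subject_stats(segs, width = config$excision_width,
                             n_max = config$n_max)
  group_summary <- summarize_cohort(segs, width = config$excision_width,
                                    n_max = config$n_max)

  # per-segment statistics, on the post-excision strides
  seg_stats <- purrr::map(segs, function(seg) {
    strides <- apply_extra_excision(seg, width = config$excision_width)
    per_param <- function(param) {
      st <- tryCatch(per_segment_stats(strides, param),
                     error = function(e) NULL)
      if (is.null(st)) return(NULL)
      mutate(st, subject_id = seg$subject_id[[1]], group = seg$group[[1]],
             parameter = param, .before = 1)
    }
    bind_rows(per_param("stride_length"), per_param("stride_time"))
  }) |> bind_rows()

  icc_tbl <- compute_segment_iccs(seg_stats)

  cum <- cohort_cumulative(segs, width = config$excision_width,
                           n_min = config$n_min, n_max = config$n_max)

  conv <- list()
  req <- list()
  for (g in unique(cum$group)) {
    for (param in c("stride_length", "stride_time")) {
      sub <- filter(cum, .data$group == g, .data$parameter == param)
      if (length(unique(sub$subject_id)) < 3) next
      for (statistic in c("cum_mean", "cum_cov")) {
        prof <- convergence_profile(sub, statistic)
        n_req <- required_stride_count(prof, threshold = config$criterion_r,
                                       sustained = config$sustained)
        conv[[length(conv) + 1L]] <- mutate(
          as_tibble(prof), group = g, parameter = param,
          statistic = statistic, .before = 1
        )
        at_n <- filter(sub, .data$n == n_req)[[statistic]]
        at_max <- filter(sub, .data$n == config$n_max)[[statistic]]
        cls_n <- classify_above_cutoff(at_n, config$cov_cutoff_pct)
        cls_max <- classify_above_cutoff(at_max, config$cov_cutoff_pct)
        req[[length(req) + 1L]] <- tibble(
          group = g, parameter = param, statistic = statistic,
          n_required = n_req,
          mean_at_n = mean(at_n), sd_at_n = stats::sd(at_n),
          n_above_cutoff_at_n = if (statistic == "cum_cov")
            cls_n$n_above else NA_integer_,
          mean_at_nmax = mean(at_max), sd_at_nmax = stats::sd(at_max),
          n_above_cutoff_at_nmax = if (statistic == "cum_cov")
            cls_max$n_above else NA_integer_,
          n_subjects = length(at_max)
        )
      }
    }
  }

  periturn <- extract_periturn_strides(segs)
  periturn_cmp <- NULL
  if (nrow(periturn) > 0) {
    ref <- periturn_reference(segs, n_ref = config$n_max,
                              width = config$excision_width)
    periturn_cmp <- periturn_comparison(normalize_periturn(periturn, ref))
  }
  log <- c(log, sprintf("peri-turn strides pooled: %d", nrow(periturn)))

  structure(
    list(
      config = config,
      qc = qc,
      subject_stats = stats_tbl,
      group_summary = group_summary,
      segment_stats = seg_stats,
      icc = icc_tbl,
      cumulative = cum,
      convergence = bind_rows(conv),
      n_required = bind_rows(req),
      periturn = periturn_cmp,
      log = log
    ),
    class = "gait_report"
  )
}

# subjects x segments ICC per group, parameter and measure; subjects with
# incomplete segment sets are dropped listwise
compute_segment_iccs <- function(seg_stats) {
  if (nrow(seg_stats) == 0) return(tibble())
  out <- list()
  for (g in unique(seg_stats$group)) {
    for (param in unique(seg_stats$parameter)) {
      sub <- filter(seg_stats, .data$group == g, .data$parameter == param)
      k <- max(sub$segment_id)
      for (measure in c("mean", "cov")) {
        wide <- sub |>
          select("subject_id", "segment_id", dplyr::all_of(measure)) |>
          tidyr::pivot_wider(names_from = "segment_id",
                             values_from = dplyr::all_of(measure)) |>
          tidyr::drop_na()
        if (nrow(wide) < 2 || ncol(wide) - 1 < 2) next
        res <- icc_two_way_random_single(as.matrix(wide[, -1]))
        out[[length(out) + 1L]] <- tibble(
          group = g, parameter = param,
          measure = paste0("segment_", measure),
          icc = res$icc, band = res$band,
          n_subjects = res$n_subjects, k_segments = res$k_segments
        )
      }
    }
  }
  bind_rows(out)
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat(sprintf("  groups: %s\n",
              paste(x$group_summary$group, collapse = ", ")))
  if (nrow(x$n_required) > 0) {
    cat("  required stride counts (statistic = cum_cov):\n")
    sub <- x$n_required[x$n_required$statistic == "cum_cov", ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %s %s: n = %d\n", sub$group[i], sub$parameter[i],
                  sub$n_required[i]))
    }
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every table of a [run_pipeline()] report as CSV plus the run log
#' as plain text into a directory.
#'
#' @param report A `gait_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gait_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("qc", "subject_stats", "group_summary", "segment_stats",
              "icc", "cumulative", "convergence", "n_required", "periturn")
  for (nm in tables) {
    tbl <- report[[nm]]
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_csv(as_tibble(tbl), file.path(dir, paste0(nm, ".csv")))
    }
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
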