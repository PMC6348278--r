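#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange group_by summarise ungroup select
#'   bind_rows left_join n row_number across
NULL

PERITURN_LEVELS <- c("none", "before_turn", "after_turn", "turning")

TRIAL_COLUMNS <- c(
  "subject_id", "group", "stride_index", "onset_s",
  "stride_length_pct_stature", "stride_time_s", "periturn_tag"
)

#' Describe a walking protocol
#'
#' A protocol specifies the geometry of a continuous over-ground walk broken
#' by 180-degree turns: how long each straight segment is, how many segments
#' are walked, and how many of the resulting turns are used when extracting
#' peri-turn strides.
#'
#' Two presets cover the study designs this package emulates:
#' [protocol_md()] is a 10 m segment walked five times (four turns, all
#' used), the protocol typically applied to movement-disorder cohorts;
#' [protocol_he()] is a 20 m segment walked back and forth (three segments,
#' two turns), of which only the first two turns are used for peri-turn
#' extraction, the design applied to large healthy-elderly cohorts.
#'
#' @param segment_length_m Length of one straight segment, in meters.
#' @param n_segments Number of straight segments walked (>= 1).
#' @param max_turns_used Cap on the number of turns used for peri-turn
#'   stride extraction. Defaults to all turns (`n_segments - 1`).
#' @param name Optional short label for the protocol.
#' @return A `protocol_spec` object (a named list with fields
#'   `segment_length_m`, `n_segments`, `expected_turns`, `max_turns_used`,
#'   `name`).
#' @examples
#' protocol_spec(10, 5)
#' protocol_he()
#' @export
protocol_spec <- function(segment_length_m, n_segments,
                          max_turns_used = n_segments - 1L,
                          name = NULL) {
  n_segments <- as.integer(n_segments)
  max_turns_used <- as.integer(max_turns_used)
  if (n_segments < 1L) abort("`n_segments` must be >= 1.")
  expected_turns <- n_segments - 1L
  if (max_turns_used > expected_turns) {
    abort("`max_turns_used` cannot exceed `n_segments` - 1.")
  }
  structure(
    list(
      segment_length_m = as.numeric(segment_length_m),
      n_segments = n_segments,
      expected_turns = expected_turns,
      max_turns_used = max_turns_used,
      name = name %||% sprintf("%gm x %d", segment_length_m, n_segments)
    ),
    class = "protocol_spec"
  )
}

#' @rdname protocol_spec
#' @export
protocol_md <- function() {
  protocol_spec(10, 5L, max_turns_used = 4L, name = "MD")
}

#' @rdname protocol_spec
#' @export
protocol_he <- function() {
  protocol_spec(20, 3L, max_turns_used = 2L, name = "HE")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "<protocol_spec '%s'> %g m x %d segments, %d turns (%d used)\n",
    x$name, x$segment_length_m, x$n_segments, x$expected_turns,
    x$max_turns_used
  ))
  invisible(x)
}

#' Construct a gait trial
#'
#' A gait trial is one subject's ordered sequence of strides exported by an
#' ambulatory gait-analysis system after (attempted) turn excision: one row
#' per stride carrying its onset timestamp, stride length normalized to
#' percent of body stature, and stride time (gait cycle time) in seconds.
#' The trial tibble also carries the walking protocol and optional stature
#' as attributes.
#'
#' @param records A data frame with columns `stride_index` (0-based,
#'   contiguous), `onset_s`, `stride_length_pct_stature`, `stride_time_s`,
#'   and optionally `periturn_tag` (one of `"none"`, `"before_turn"`,
#'   `"after_turn"`, `"turning"`; defaults to `"none"`).
#' @param subject_id Opaque subject label.
#' @param group Cohort label, e.g. `"HE"`, `"ATX"`, `"ET"`, `"PD"`.
#' @param protocol A [protocol_spec()].
#' @param stature_m Optional body height in meters (metadata only; lengths
#'   are already stored in percent stature).
#' @return A tibble of class `gait_trial` with columns `subject_id`,
#'   `group`, `stride_index`, `onset_s`, `stride_length_pct_stature`,
#'   `stride_time_s`, `periturn_tag`, sorted by `onset_s`, with attributes
#'   `protocol` and `stature_m`.
#' @seealso [read_trial_table()], [validate_trial()]
#' @export
gait_trial <- function(records, subject_id, group, protocol,
                       stature_m = NA_real_) {
  stopifnot(inherits(protocol, "protocol_spec"))
  records <- as_tibble(records)
  needed <- c("onset_s", "stride_length_pct_stature", "stride_time_s")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing stride columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(records) == 0) abort("A gait trial needs at least one stride.")
  if (!"periturn_tag" %in% names(records)) {
    records$periturn_tag <- "none"
  }
  bad_tag <- setdiff(unique(records$periturn_tag), PERITURN_LEVELS)
  if (length(bad_tag) > 0) {
    abort(paste0("Unknown periturn_tag value(s): ",
                 paste(bad_tag, collapse = ", ")))
  }
  if (is.unsorted(records$onset_s, strictly = TRUE)) {
    warn("Stride onsets out of order; re-sorting by `onset_s`.")
    records <- arrange(records, .data$onset_s)
  }
  out <- tibble(
    subject_id = as.character(subject_id),
    group = as.character(group),
    stride_index = seq_len(nrow(records)) - 1L,
    onset_s = as.numeric(records$onset_s),
    stride_length_pct_stature = as.numeric(records$stride_length_pct_stature),
    stride_time_s = as.numeric(records$stride_time_s),
    periturn_tag = as.character(records$periturn_tag)
  )
  new_gait_trial(out, protocol, stature_m)
}

new_gait_trial <- function(tbl, protocol, stature_m = NA_real_) {
  structure(
    tbl,
    protocol = protocol,
    stature_m = stature_m,
    class = c("gait_trial", class(tibble()))
  )
}

#' Retrieve the protocol attached to a trial
#'
#' @param trial A `gait_trial`.
#' @return The [protocol_spec()] stored on the trial.
#' @export
trial_protocol <- function(trial) {
  attr(trial, "protocol", exact = TRUE)
}

#' Read / write a stride table
#'
#' The on-disk dialect is a plain UTF-8 CSV with a header row and `.` as
#' decimal separator, columns `subject_id`, `group`, `stride_index`,
#' `onset_s`, `stride_length_pct_stature`, `stride_time_s`, `periturn_tag`.
#' `read_trial_table()` validates the schema and the stride invariants
#' (positive times and lengths, non-negative onsets) and re-sorts by onset
#' with a warning if rows are out of order; `write_trial_table()` writes a
#' trial back at full precision, so that a write/read round trip reproduces
#' the records exactly.
#'
#' @param path File location of the CSV stride table.
#' @param protocol A [protocol_spec()] describing the walk the table records.
#' @return `read_trial_table()` returns a [gait_trial()];
#'   `write_trial_table()` returns `path` invisibly.
#' @examples
#' tr <- generate_trial(cohort_profile("HE"), generator_config(protocol_he()),
#'                      subject_seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trial_table(tr, f)
#' tr2 <- read_trial_table(f, protocol_he())
#' all.equal(as.data.frame(tr), as.data.frame(tr2))
#' @export
read_trial_table <- function(path, protocol) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Stride table ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(names(raw)) > 0) {
    abort(paste0("Stride table ", path, " has duplicated columns."))
  }
  if (nrow(raw) == 0) abort(paste0("Stride table ", path, " has no rows."))
  bad <- which(raw$stride_time_s <= 0 | raw$stride_length_pct_stature <= 0 |
                 raw$onset_s < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid stride values in %s at data row(s) %s (need onset_s >= 0, stride_time_s > 0, stride_length_pct_stature > 0).",
      path, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  gait_trial(
    raw[, c("stride_index", "onset_s", "stride_length_pct_stature",
            "stride_time_s", "periturn_tag")],
    subject_id = raw$subject_id[[1]],
    group = raw$group[[1]],
    protocol = protocol
  )
}

#' @rdname read_trial_table
#' @param trial A valid [gait_trial()] with at least one record.
#' @export
write_trial_table <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  if (nrow(trial) == 0) abort("Refusing to write an empty trial.")
  readr::write_csv(as_tibble(trial)[, TRIAL_COLUMNS], path)
  invisible(path)
}

#' Validate a gait trial against the analysis prerequisites
#'
#' Checks the stride-record invariants (strictly increasing onsets,
#' contiguous 0-based indices, positive times and lengths) and that the
#' trial contains at least `min_strides` strides — 40 gait cycles being the
#' usual floor for cross-cohort comparability of variability measures.
#' Violations are reported, never raised.
#'
#' @param trial A `gait_trial`.
#' @param min_strides Minimum acceptable stride count (default 40).
#' @return A tibble of issues with columns `issue` and `detail`; zero rows
#'   when the trial is clean.
#' @examples
#' tr <- generate_trial(cohort_profile("HE"), generator_config(protocol_he()),
#'                      subject_seed = 1)
#' validate_trial(tr)
#' @export
validate_trial <- function(trial, min_strides = 40L) {
  issues <- list()
  add <- function(issue, detail) {
    issues[[length(issues) + 1L]] <<- tibble(issue = issue, detail = detail)
  }
  if (nrow(trial) < min_strides) {
    add("too_few_strides",
        sprintf("%d strides, need >= %d", nrow(trial), min_strides))
  }
  if (nrow(trial) > 1 && is.unsorted(trial$onset_s, strictly = TRUE)) {
    add("onsets_not_increasing", "onset_s must be strictly increasing")
  }
  if (!identical(trial$stride_index, seq_len(nrow(trial)) - 1L)) {
    add("indices_not_contiguous", "stride_index must run 0..n-1")
  }
  bad_t <- which(trial$stride_time_s <= 0)
  if (length(bad_t) > 0) {
    add("nonpositive_stride_time",
        paste0("rows ", paste(utils::head(bad_t, 5), collapse = ", ")))
  }
  bad_l <- which(trial$stride_length_pct_stature <= 0)
  if (length(bad_l) > 0) {
    add("nonpositive_stride_length",
        paste0("rows ", paste(utils::head(bad_l, 5), collapse = ", ")))
  }
  if (any(trial$onset_s < 0)) add("negative_onset", "onset_s must be >= 0")
  if (length(issues) == 0) {
    tibble(issue = character(), detail = character())
  } else {
    bind_rows(issues)
  }
}

#' Read a cohort manifest and load its trials
#'
#' A cohort manifest is a CSV listing one trial per row: `subject_id`,
#' `group`, `path` (stride-table location, relative paths resolved against
#' the manifest's directory) and `protocol` (`"MD"` or `"HE"`).
#'
#' @param path Manifest CSV location.
#' @return A list of [gait_trial()] objects, named by subject id.
#' @seealso [write_cohort()]
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "group", "path", "protocol")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols) > 0) {
    abort(paste0("Manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  base <- dirname(path)
  trials <- purrr::pmap(man, function(subject_id, group, path, protocol, ...) {
    proto <- switch(protocol,
      MD = protocol_md(),
      HE = protocol_he(),
      abort(paste0("Unknown protocol name: ", protocol))
    )
    p <- if (file.exists(path)) path else file.path(base, path)
    read_trial_table(p, proto)
  })
  names(trials) <- man$subject_id
  trials
}

#' Write a cohort of trials plus manifest to a directory
#'
#' @param trials A list of [gait_trial()] objects.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map(trials, function(tr) {
    proto <- trial_protocol(tr)
    fname <- paste0(tr$subject_id[[1]], ".csv")
    write_trial_table(tr, file.path(dir, fname))
    tibble(
      subject_id = tr$subject_id[[1]], group = tr$group[[1]],
      path = fname, protocol = proto$name
    )
  })
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(bind_rows(rows), manifest)
  invisible(manifest)
}
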