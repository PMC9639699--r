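# Canonical column sets and enumerations for the CSV dialects.
CONDITIONS <- c("central", "peripheral", "control")
SCENE_TYPES <- c("natural", "urban")
EVENT_KINDS <- c("fixation", "saccade", "blink")

SAMPLES_HEADER <- c("participant_id", "trial_index", "condition",
                    "scene_type", "t_ms", "x_px", "y_px", "pupil")
EVENTS_HEADER <- c("participant_id", "trial_index", "event_kind",
                   "onset_ms", "offset_ms", "duration_ms",
                   "x_start_px", "y_start_px", "x_end_px", "y_end_px",
                   "amplitude_deg")
MANIFEST_HEADER <- c("participant_id", "trial_index", "condition",
                     "scene_type", "scene_id")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_integer_ms <- function(x, what) {
  bad <- is.finite(x) & x != round(x)
  if (any(bad)) {
    stop(sprintf("%s must be integer milliseconds; fractional values found (e.g. %s)",
                 what, format(x[bad][1])), call. = FALSE)
  }
  as.integer(round(x))
}

check_conditions <- function(x) {
  bad <- setdiff(unique(x), CONDITIONS)
  if (length(bad)) {
    stop("unknown condition token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read gaze sample streams
#'
#' Reads raw 1000 Hz gaze samples in either the package's CSV dialect or a
#' minimal EyeLink-ASC-like text subset, returning one tidy tibble with one
#' row per sample. The CSV dialect has the exact header
#' `participant_id,trial_index,condition,scene_type,t_ms,x_px,y_px,pupil`;
#' `"."` or an empty field encodes a missing coordinate or pupil value.
#'
#' In the `asc_subset` dialect a line
#' `MSG <t> TRIALID <participant>_<trial>_<condition>_<scenetype>` opens a
#' trial and subsequent sample lines `t<TAB>x<TAB>y<TAB>pupil` are offset
#' by the TRIALID timestamp. Native `EFIX`/`ESACC`/`EBLINK` event lines are
#' ignored: events are re-detected from the samples, not trusted.
#'
#' Timestamps must be integer milliseconds and strictly increasing within
#' a trial; fractional timestamps are rejected rather than silently
#' rounded, since rounding hides sample-rate errors.
#'
#' @param file Path to the input file, or literal text wrapped in [I()].
#' @param dialect `"csv"` or `"asc_subset"`.
#' @return A tibble with the sample columns above; `trial_index` and
#'   `t_ms` are integers, coordinates and pupil are doubles with `NA` for
#'   missing. An empty stream yields a zero-row tibble.
#' @export
read_gaze_samples <- function(file, dialect = c("csv", "asc_subset")) {
  dialect <- match.arg(dialect)
  smp <- if (dialect == "csv") read_samples_csv(file) else read_samples_asc(file)
  check_conditions(smp$condition)
  validate_monotone(smp)
  smp
}

read_samples_csv <- function(file) {
  smp <- readr::read_csv(
    file,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_index = readr::col_double(),
      condition = readr::col_character(),
      scene_type = readr::col_character(),
      t_ms = readr::col_double(),
      x_px = readr::col_double(),
      y_px = readr::col_double(),
      pupil = readr::col_double()
    ),
    na = c("", ".", "NA"), progress = FALSE
  )
  if (!identical(names(smp), SAMPLES_HEADER)) {
    stop("samples CSV header must be exactly: ",
         paste(SAMPLES_HEADER, collapse = ","), call. = FALSE)
  }
  smp$t_ms <- assert_integer_ms(smp$t_ms, "t_ms")
  smp$trial_index <- as.integer(smp$trial_index)
  smp
}

read_samples_asc <- function(file) {
  lines <- readr::read_lines(file, progress = FALSE)
  trial_re <- "^MSG\\s+(\\d+)\\s+TRIALID\\s+([^_\\s]+)_(\\d+)_([^_\\s]+)_([^_\\s]+)\\s*$"
  sample_re <- "^([0-9.]+)\\t([0-9.eE+-]*|\\.)\\t([0-9.eE+-]*|\\.)\\t([0-9.eE+-]*|\\.)\\s*$"
  out <- vector("list", length(lines))
  meta <- NULL
  onset <- NA_real_
  n_out <- 0L
  for (ln in lines) {
    if (grepl(trial_re, ln)) {
      m <- regmatches(ln, regexec(trial_re, ln))[[1]]
      onset <- as.numeric(m[2])
      meta <- list(participant_id = m[3], trial_index = as.integer(m[4]),
                   condition = m[5], scene_type = m[6])
    } else if (!is.null(meta) && grepl(sample_re, ln)) {
      m <- regmatches(ln, regexec(sample_re, ln))[[1]]
      num <- function(s) if (s == "." || s == "") NA_real_ else as.numeric(s)
      t_abs <- as.numeric(m[2])
      n_out <- n_out + 1L
      out[[n_out]] <- list(
        participant_id = meta$participant_id,
        trial_index = meta$trial_index,
        condition = meta$condition,
        scene_type = meta$scene_type,
        t_ms = t_abs - onset,
        x_px = num(m[3]), y_px = num(m[4]), pupil = num(m[5])
      )
    }
    # all other lines (EFIX/ESACC/EBLINK, preamble, blank) are ignored
  }
  if (n_out == 0L) {
    return(tibble::tibble(
      participant_id = character(), trial_index = integer(),
      condition = character(), scene_type = character(),
      t_ms = integer(), x_px = double(), y_px = double(), pupil = double()
    ))
  }
  smp <- dplyr::bind_rows(out[seq_len(n_out)])
  smp$t_ms <- assert_integer_ms(smp$t_ms, "t_ms")
  smp
}

validate_monotone <- function(smp) {
  if (nrow(smp) == 0) return(invisible(smp))
  bad <- smp |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::summarise(mono = all(diff(.data$t_ms) > 0), .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(bad)) {
    stop(sprintf("non-monotone timestamps in trial (%s, %d)",
                 bad$participant_id[1], bad$trial_index[1]), call. = FALSE)
  }
  if (any(smp$t_ms < 0)) {
    stop("negative t_ms found; timestamps are relative to trial onset",
         call. = FALSE)
  }
  invisible(smp)
}

#' Write gaze samples in the CSV dialect
#'
#' @param samples Tibble as returned by [read_gaze_samples()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gaze_samples <- function(samples, file) {
  stopifnot(identical(names(samples)[seq_along(SAMPLES_HEADER)], SAMPLES_HEADER))
  fmt <- function(x) ifelse(is.na(x), ".", as.character(signif(x, 6)))
  lines <- paste(
    samples$participant_id, samples$trial_index, samples$condition,
    samples$scene_type, samples$t_ms,
    fmt(samples$x_px), fmt(samples$y_px), fmt(samples$pupil),
    sep = ","
  )
  readr::write_lines(c(paste(SAMPLES_HEADER, collapse = ","), lines), file)
  invisible(file)
}

#' Construct / validate an event table
#'
#' The event table is the pipeline's central container: one row per
#' detected fixation, saccade or blink. Positions are screen pixels;
#' `amplitude_deg` is the start-to-end angular distance of a saccade and
#' `NA` for other kinds.
#'
#' @param participant_id,trial_index,event_kind,onset_ms,offset_ms Vectors
#'   of equal length (recycled where length one).
#' @param x_start_px,y_start_px,x_end_px,y_end_px,amplitude_deg Optional
#'   numeric vectors, `NA` by default.
#' @return A validated tibble with the canonical event columns and
#'   `duration_ms = offset_ms - onset_ms`.
#' @export
event_table <- function(participant_id = character(), trial_index = integer(),
                        event_kind = character(), onset_ms = integer(),
                        offset_ms = integer(),
                        x_start_px = NA_real_, y_start_px = NA_real_,
                        x_end_px = NA_real_, y_end_px = NA_real_,
                        amplitude_deg = NA_real_) {
  ev <- tibble::tibble(
    participant_id = as.character(participant_id),
    trial_index = as.integer(trial_index),
    event_kind = as.character(event_kind),
    onset_ms = as.integer(onset_ms),
    offset_ms = as.integer(offset_ms),
    duration_ms = as.integer(offset_ms) - as.integer(onset_ms),
    x_start_px = as.numeric(x_start_px),
    y_start_px = as.numeric(y_start_px),
    x_end_px = as.numeric(x_end_px),
    y_end_px = as.numeric(y_end_px),
    amplitude_deg = as.numeric(amplitude_deg)
  )
  validate_event_table(ev)
}

validate_event_table <- function(events) {
  stopifnot(all(EVENTS_HEADER %in% names(events)))
  if (any(events$offset_ms <= events$onset_ms)) {
    stop("event table invalid: offset_ms must exceed onset_ms", call. = FALSE)
  }
  if (any(events$duration_ms != events$offset_ms - events$onset_ms)) {
    stop("event table invalid: duration_ms != offset_ms - onset_ms",
         call. = FALSE)
  }
  bad <- setdiff(unique(events$event_kind), EVENT_KINDS)
  if (length(bad)) {
    stop("unknown event_kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  amp <- events$amplitude_deg
  if (any(!is.na(amp) & amp < 0)) {
    stop("event table invalid: negative amplitude_deg", call. = FALSE)
  }
  events
}

#' Write an event table as CSV
#'
#' Deterministic formatting: millisecond columns as integers, degree and
#' pixel columns at 6 significant digits, missing values as empty fields,
#' LF line endings. Reading the output back with [read_event_table()]
#' reproduces the table.
#'
#' @param events An event table (see [event_table()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_event_table <- function(events, file) {
  validate_event_table(events)
  fmt <- function(x) ifelse(is.na(x), "", as.character(signif(x, 6)))
  lines <- paste(
    events$participant_id, events$trial_index, events$event_kind,
    events$onset_ms, events$offset_ms, events$duration_ms,
    fmt(events$x_start_px), fmt(events$y_start_px),
    fmt(events$x_end_px), fmt(events$y_end_px),
    fmt(events$amplitude_deg),
    sep = ","
  )
  readr::write_lines(c(paste(EVENTS_HEADER, collapse = ","), lines), file)
  invisible(file)
}

#' Read an event table CSV
#'
#' @param file Path or literal text wrapped in [I()].
#' @return A validated event-table tibble.
#' @export
read_event_table <- function(file) {
  ev <- readr::read_csv(
    file,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_index = readr::col_integer(),
      event_kind = readr::col_character(),
      onset_ms = readr::col_integer(),
      offset_ms = readr::col_integer(),
      duration_ms = readr::col_integer(),
      .default = readr::col_double()
    ),
    na = c("", ".", "NA"), progress = FALSE
  )
  if (!identical(names(ev), EVENTS_HEADER)) {
    stop("events CSV header must be exactly: ",
         paste(EVENTS_HEADER, collapse = ","), call. = FALSE)
  }
  validate_event_table(ev)
}

#' Read a trial manifest
#'
#' The manifest lists every trial of the experiment with its participant,
#' visual condition (`central`, `peripheral`, `control`) and scene type
#' (`natural`, `urban`). In strict mode each participant must have the
#' full design: 90 trials, 30 per condition, 15 natural + 15 urban within
#' each condition.
#'
#' @param file Path or literal text wrapped in [I()].
#' @param strict If `TRUE`, validate per-participant design counts and
#'   fail listing every deviation.
#' @return A tibble with columns
#'   `participant_id, trial_index, condition, scene_type, scene_id`.
#' @export
read_trial_manifest <- function(file, strict = FALSE) {
  mf <- readr::read_csv(
    file,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_index = readr::col_integer(),
      condition = readr::col_character(),
      scene_type = readr::col_character(),
      scene_id = readr::col_character()
    ),
    progress = FALSE
  )
  if (!identical(names(mf), MANIFEST_HEADER)) {
    stop("manifest CSV header must be exactly: ",
         paste(MANIFEST_HEADER, collapse = ","), call. = FALSE)
  }
  check_conditions(mf$condition)
  bad_scene <- setdiff(unique(mf$scene_type), SCENE_TYPES)
  if (length(bad_scene)) {
    stop("unknown scene_type token(s): ", paste(bad_scene, collapse = ", "),
         call. = FALSE)
  }
  if (strict) validate_manifest_design(mf)
  mf
}

validate_manifest_design <- function(mf) {
  if (nrow(mf) == 0) return(invisible(mf))
  msgs <- character()
  for (pid in unique(mf$participant_id)) {
    sub <- mf[mf$participant_id == pid, ]
    if (nrow(sub) != 90) {
      msgs <- c(msgs, sprintf("%s: %d trials (expected 90)", pid, nrow(sub)))
    }
    for (cond in CONDITIONS) {
      cc <- sub[sub$condition == cond, ]
      if (nrow(cc) != 30) {
        msgs <- c(msgs, sprintf("%s/%s: %d trials (expected 30)",
                                pid, cond, nrow(cc)))
      }
      for (st in SCENE_TYPES) {
        n_st <- sum(cc$scene_type == st)
        if (n_st != 15) {
          msgs <- c(msgs, sprintf("%s/%s/%s: %d trials (expected 15)",
                                  pid, cond, st, n_st))
        }
      }
    }
  }
  if (length(msgs)) {
    stop("manifest design validation failed:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  invisible(mf)
}

#' Write a trial manifest
#' @param manifest Manifest tibble (see [read_trial_manifest()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trial_manifest <- function(manifest, file) {
  stopifnot(identical(names(manifest)[seq_along(MANIFEST_HEADER)],
                      MANIFEST_HEADER))
  lines <- paste(manifest$participant_id, manifest$trial_index,
                 manifest$condition, manifest$scene_type, manifest$scene_id,
                 sep = ",")
  readr::write_lines(c(paste(MANIFEST_HEADER, collapse = ","), lines), file)
  invisible(file)
}
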