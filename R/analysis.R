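#' Classify fixations as ambient or focal
#'
#' A fixation is labelled by the amplitude of the saccade that brought
#' the eye to it: `ambient` when the preceding saccade's amplitude is
#' strictly greater than `threshold_deg` (large exploratory relocation),
#' `focal` when it is at or below the threshold (local scrutiny), and
#' `unclassified` when no saccade directly abuts the fixation onset
#' (e.g. the first fixation of a trial, or the preceding saccade was
#' removed during cleaning). Amplitudes exactly at the threshold fall to
#' `focal` by convention.
#'
#' @param events Event table; the preceding-saccade amplitude is derived
#'   from saccade rows whose offset equals a fixation's onset within the
#'   same trial.
#' @param threshold_deg Classification threshold in degrees; 5 by
#'   default, the central/peripheral visual-field boundary.
#' @return `events` with two added columns on fixation rows:
#'   `preceding_saccade_amplitude_deg` and
#'   `fixation_type` (`"ambient"`, `"focal"`, `"unclassified"`); `NA` on
#'   other rows.
#' @export
classify_fixations <- function(events, threshold_deg = 5) {
  sacc <- events[events$event_kind == "saccade",
                 c("participant_id", "trial_index", "offset_ms",
                   "amplitude_deg")]
  names(sacc)[3:4] <- c("onset_ms", "preceding_saccade_amplitude_deg")
  sacc <- dplyr::distinct(sacc, .data$participant_id, .data$trial_index,
                          .data$onset_ms, .keep_all = TRUE)
  out <- dplyr::left_join(
    events, sacc,
    by = c("participant_id", "trial_index", "onset_ms")
  )
  amp <- out$preceding_saccade_amplitude_deg
  is_fix <- out$event_kind == "fixation"
  out$preceding_saccade_amplitude_deg[!is_fix] <- NA_real_
  out$fixation_type <- ifelse(
    !is_fix, NA_character_,
    ifelse(is.na(amp), "unclassified",
           ifelse(amp > threshold_deg, "ambient", "focal"))
  )
  out
}

#' Default early/late viewing intervals
#'
#' Early viewing is the first two seconds of a trial; late viewing is the
#' 6-8 s window, by which time fixation durations have reached asymptote
#' in all visual conditions.
#'
#' @param early,late Numeric length-2 half-open intervals `[lo, hi)`, ms.
#' @return An object of class `interval_spec`.
#' @export
interval_spec <- function(early = c(0, 2000), late = c(6000, 8000)) {
  stopifnot(length(early) == 2, length(late) == 2,
            early[1] < early[2], late[1] < late[2])
  if (max(early[1], late[1]) < min(early[2], late[2])) {
    stop("early and late intervals must be disjoint", call. = FALSE)
  }
  structure(list(early = early, late = late), class = "interval_spec")
}

#' Tag events as early, late, or neither
#'
#' Membership is decided by event onset: an event belongs to an interval
#' iff its onset lies within the half-open interval, so an event
#' straddling a boundary counts with the interval it started in.
#'
#' @param events Event table.
#' @param spec An [interval_spec()].
#' @return `events` with an added `interval` column
#'   (`"early"`, `"late"`, `"neither"`).
#' @export
interval_slice <- function(events, spec = interval_spec()) {
  on <- events$onset_ms
  events$interval <- ifelse(
    on >= spec$early[1] & on < spec$early[2], "early",
    ifelse(on >= spec$late[1] & on < spec$late[2], "late", "neither")
  )
  events
}

#' Per-participant summary table
#'
#' Aggregates cleaned, classified, sliced events into the tidy
#' per-participant table consumed by standard repeated-measures
#' statistics: one row per participant x factor cell with the mean
#' fixation duration over that cell's fixations, the mean saccade
#' amplitude over its saccades, and the event count. Cells with no
#' events appear with `n_events = 0` and missing means.
#'
#' @param events Event table with any factor columns already present
#'   (join the manifest for `condition`/`scene_type`, run
#'   [classify_fixations()] and [interval_slice()] first as needed).
#' @param factors Character vector, subset of
#'   `c("condition", "scene_type", "interval", "fixation_type")`. When
#'   `"interval"` is used, events tagged `"neither"` are dropped first.
#' @return A tibble with `participant_id`, the factor columns,
#'   `mean_fd_ms`, `mean_sa_deg`, `n_events`, in deterministic order.
#' @export
aggregate_events <- function(events, factors = "condition") {
  allowed <- c("condition", "scene_type", "interval", "fixation_type")
  stopifnot(all(factors %in% allowed), all(factors %in% names(events)))
  ev <- events[events$event_kind %in% c("fixation", "saccade"), ]
  if ("interval" %in% factors) ev <- ev[ev$interval != "neither", ]
  # the fixation-type factor only applies to fixations
  if ("fixation_type" %in% factors) ev <- ev[!is.na(ev$fixation_type), ]
  grp <- c("participant_id", factors)
  tab <- ev |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_fd_ms = mean(.data$duration_ms[.data$event_kind == "fixation"]),
      mean_sa_deg = mean(.data$amplitude_deg[.data$event_kind == "saccade"]),
      n_events = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(!!!rlang::syms(grp), fill = list(n_events = 0L)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
  tab
}

#' Grand means across participants
#'
#' Collapses a participant-level summary table to unweighted grand means
#' of the participant cell means (each participant counts once,
#' regardless of event count).
#'
#' @param summary_table Output of [aggregate_events()].
#' @return One row per factor cell with `mean_fd_ms`, `mean_sa_deg` and
#'   `n_participants`.
#' @export
grand_means <- function(summary_table) {
  factors <- setdiff(names(summary_table),
                     c("participant_id", "mean_fd_ms", "mean_sa_deg",
                       "n_events"))
  summary_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::summarise(
      n_participants = sum(!is.na(.data$mean_fd_ms) |
                             !is.na(.data$mean_sa_deg)),
      mean_fd_ms = mean(.data$mean_fd_ms, na.rm = TRUE),
      mean_sa_deg = mean(.data$mean_sa_deg, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(factors), "mean_fd_ms", "mean_sa_deg",
                  "n_participants") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(factors)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates detection (when raw samples are given), cleaning,
#' ambient/focal classification, early/late slicing, 500-ms binning, the
#' asymptote fits with time-to-asymptote, and the per-participant
#' aggregation tables. Fully deterministic given its inputs.
#'
#' @param samples Raw gaze samples (tibble) or `NULL` when `events` are
#'   supplied directly.
#' @param events Pre-detected event table; ignored when `samples` given.
#' @param manifest Trial manifest tibble (provides `condition` and
#'   `scene_type`); when `NULL` these columns are taken from `samples`.
#' @param geometry,detection,cleaning Parameter objects
#'   ([screen_geometry()], [detection_params()], [cleaning_params()]).
#' @param intervals An [interval_spec()].
#' @param threshold_deg Ambient/focal classification threshold, degrees.
#' @param bin_ms Time-course bin width, ms.
#' @param skip_bins_fd,skip_bins_sa Bins excluded from the fixation-
#'   duration and saccade-amplitude fits.
#' @param t_label Bin time labelling, `"end"` or `"midpoint"`.
#' @param max_bins Drop bins beyond this index before fitting (keeps the
#'   fit on the full-viewing-time lattice; 40 covers a 20-s trial).
#' @param output_dir When given, writes `clean_events.csv`,
#'   `cleaning_report.csv`, `timecourse_{fd,sa}.csv`, `fits.csv` and
#'   `summary_*.csv` there.
#' @return A list of class `af_pipeline`: `events` (clean, classified,
#'   sliced), `cleaning` (full [clean_events()] result), `timecourses`
#'   (per-condition and pooled, both measures), `fits` (tibble of
#'   per-condition and pooled `b`, `a`, CI and reach time), `summaries`
#'   (named list of participant-level tables).
#' @export
run_pipeline <- function(samples = NULL, events = NULL, manifest = NULL,
                         geometry = screen_geometry(),
                         detection = detection_params(),
                         cleaning = cleaning_params(),
                         intervals = interval_spec(),
                         threshold_deg = 5, bin_ms = 500,
                         skip_bins_fd = 0, skip_bins_sa = 2,
                         t_label = "end", max_bins = 40,
                         output_dir = NULL) {
  if (is.null(samples) && is.null(events)) {
    stop("supply either samples or events", call. = FALSE)
  }
  if (!is.null(samples)) {
    events <- detect_events(samples, geometry, detection)
    if (is.null(manifest)) {
      manifest <- dplyr::distinct(samples, .data$participant_id,
                                  .data$trial_index, .data$condition,
                                  .data$scene_type)
    }
  }
  if (is.null(manifest)) {
    stop("a manifest is required when starting from events", call. = FALSE)
  }
  meta <- dplyr::distinct(manifest, .data$participant_id,
                          .data$trial_index, .data$condition,
                          .data$scene_type)

  cl <- clean_events(events, cleaning)
  ev <- cl$events |>
    dplyr::left_join(meta, by = c("participant_id", "trial_index")) |>
    classify_fixations(threshold_deg) |>
    interval_slice(intervals)

  fit_group <- function(measure, skip) {
    tc_all <- bin_events(ev, measure, bin_ms, by = NULL, t_label)
    tc_cond <- bin_events(ev, measure, bin_ms, by = "condition", t_label)
    groups <- c(list(pooled = tc_all),
                split(tc_cond, tc_cond$condition))
    rows <- purrr::imap(groups, function(tc, nm) {
      tc <- tc[tc$bin_index <= max_bins, ]
      fit <- fit_asymptote(tc, skip_bins = skip)
      tibble::tibble(
        measure = measure, group = nm,
        b = fit$b, a = fit$a,
        b_ci_lo = fit$b_ci[1], b_ci_hi = fit$b_ci[2],
        converged = fit$converged,
        reach_time_s = if (fit$converged) reach_time(fit, tc) else NA_real_
      )
    })
    list(tc = list(pooled = tc_all, by_condition = tc_cond),
         fits = dplyr::bind_rows(rows))
  }
  fd <- fit_group("fixation_duration_ms", skip_bins_fd)
  sa <- fit_group("saccade_amplitude_deg", skip_bins_sa)

  summaries <- list(
    condition = aggregate_events(ev, "condition"),
    condition_scene = aggregate_events(ev, c("condition", "scene_type")),
    condition_interval = aggregate_events(ev, c("condition", "interval")),
    condition_fixation_type =
      aggregate_events(ev, c("condition", "fixation_type"))
  )

  res <- structure(
    list(events = ev, cleaning = cl,
         timecourses = list(fixation_duration = fd$tc,
                            saccade_amplitude = sa$tc),
         fits = dplyr::bind_rows(fd$fits, sa$fits),
         summaries = summaries),
    class = "af_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_event_table(res$events[, EVENTS_HEADER],
                    file.path(dir, "clean_events.csv"))
  readr::write_csv(res$cleaning$report,
                   file.path(dir, "cleaning_report.csv"))
  readr::write_csv(res$timecourses$fixation_duration$by_condition,
                   file.path(dir, "timecourse_fd.csv"))
  readr::write_csv(res$timecourses$saccade_amplitude$by_condition,
                   file.path(dir, "timecourse_sa.csv"))
  readr::write_csv(res$fits, file.path(dir, "fits.csv"))
  for (nm in names(res$summaries)) {
    readr::write_csv(res$summaries[[nm]],
                     file.path(dir, paste0("summary_", nm, ".csv")))
  }
  invisible(dir)
}

#' @export
print.af_pipeline <- function(x, ...) {
  cat("<af_pipeline>\n")
  cat(sprintf("  events kept: %d (%.1f%% excluded by cleaning)\n",
              sum(x$events$event_kind != "blink"), x$cleaning$total_pct))
  cat("  fits:\n")
  print(x$fits)
  invisible(x)
}
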