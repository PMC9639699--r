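#' Event-cleaning parameters
#'
#' Thresholds of the four-stage exclusion cascade: events starting before
#' trial onset, events within `blink_window_ms` of a blink, fixations
#' outside `[min_fix_ms, max_fix_ms]` (bounds kept), and trials whose
#' total blink time is `>= max_trial_blink_ms` (20% of a 20-s trial).
#'
#' @param blink_window_ms Minimum allowed gap between an event and a
#'   blink, ms.
#' @param min_fix_ms,max_fix_ms Inclusive fixation-duration bounds, ms.
#' @param max_trial_blink_ms Trials with at least this much total blink
#'   time are excluded.
#' @param trial_onset_ms Time of scene onset; events starting earlier are
#'   dropped.
#' @return An object of class `cleaning_params`.
#' @export
cleaning_params <- function(blink_window_ms = 100, min_fix_ms = 80,
                            max_fix_ms = 1000, max_trial_blink_ms = 4000,
                            trial_onset_ms = 0) {
  stopifnot(blink_window_ms >= 0, min_fix_ms > 0, min_fix_ms < max_fix_ms,
            max_trial_blink_ms > 0)
  structure(list(blink_window_ms = blink_window_ms, min_fix_ms = min_fix_ms,
                 max_fix_ms = max_fix_ms,
                 max_trial_blink_ms = max_trial_blink_ms,
                 trial_onset_ms = trial_onset_ms),
            class = "cleaning_params")
}

#' Drop events that started before scene onset
#'
#' @param events Event table rows (fixations/saccades).
#' @param trial_onset_ms Scene-onset time; an event with
#'   `onset_ms < trial_onset_ms` is removed. Onset exactly at scene onset
#'   is kept.
#' @return `list(kept, removed)`, both event tables, order preserved.
#' @export
drop_pre_onset <- function(events, trial_onset_ms = 0) {
  drop <- events$onset_ms < trial_onset_ms
  list(kept = events[!drop, ], removed = events[drop, ])
}

#' Drop events within a temporal window of any blink
#'
#' The gap between an event interval `[onset, offset)` and a blink
#' interval is the distance between the two intervals (0 if they
#' overlap); the event is removed iff the gap to any blink in the same
#' trial is strictly less than `window_ms`.
#'
#' @param events Fixation/saccade rows of an event table.
#' @param blinks Blink rows (same table format), non-overlapping per
#'   trial.
#' @param window_ms Exclusion window, ms.
#' @return `list(kept, removed)`.
#' @export
drop_blink_adjacent <- function(events, blinks, window_ms = 100) {
  if (nrow(events) == 0 || nrow(blinks) == 0) {
    return(list(kept = events, removed = events[0, ]))
  }
  key_e <- paste(events$participant_id, events$trial_index)
  key_b <- paste(blinks$participant_id, blinks$trial_index)
  drop <- logical(nrow(events))
  for (k in unique(key_e)) {
    bi <- key_b == k
    if (!any(bi)) next
    ei <- which(key_e == k)
    b_on <- blinks$onset_ms[bi]; b_off <- blinks$offset_ms[bi]
    for (i in ei) {
      gap <- interval_gap(events$onset_ms[i], events$offset_ms[i], b_on, b_off)
      drop[i] <- any(gap < window_ms)
    }
  }
  list(kept = events[!drop, ], removed = events[drop, ])
}

# distance between [on, off) and each [b_on, b_off); 0 when overlapping
interval_gap <- function(on, off, b_on, b_off) {
  pmax(0, pmax(b_on - off, on - b_off))
}

#' Filter fixations by duration bounds
#'
#' Removes fixations strictly shorter than `min_ms` or strictly longer
#' than `max_ms`; durations exactly at a bound are kept. Non-fixation
#' rows pass through untouched.
#'
#' @param events Event table rows.
#' @param min_ms,max_ms Inclusive bounds, ms.
#' @return `list(kept, removed)`.
#' @export
filter_fix_duration <- function(events, min_ms = 80, max_ms = 1000) {
  is_fix <- events$event_kind == "fixation"
  drop <- is_fix & (events$duration_ms < min_ms | events$duration_ms > max_ms)
  list(kept = events[!drop, ], removed = events[drop, ])
}

#' Exclude trials with excessive total blink time
#'
#' A trial is excluded when the summed duration of its blinks is greater
#' than or equal to `max_trial_blink_ms` (inclusive bound).
#'
#' @param events Full event table including blink rows.
#' @param max_trial_blink_ms Exclusion threshold, ms.
#' @return `list(kept, removed, excluded_trials)` where `excluded_trials`
#'   is a tibble of `(participant_id, trial_index, total_blink_ms)`.
#' @export
exclude_trials <- function(events, max_trial_blink_ms = 4000) {
  blink_tot <- events |>
    dplyr::filter(.data$event_kind == "blink") |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::summarise(total_blink_ms = sum(.data$duration_ms),
                     .groups = "drop") |>
    dplyr::filter(.data$total_blink_ms >= max_trial_blink_ms)
  key_e <- paste(events$participant_id, events$trial_index)
  key_x <- paste(blink_tot$participant_id, blink_tot$trial_index)
  drop <- key_e %in% key_x
  list(kept = events[!drop, ], removed = events[drop, ],
       excluded_trials = blink_tot)
}

#' Apply the full event-exclusion cascade
#'
#' Stages run in a fixed order: (1) events starting before scene onset,
#' (2) events within `blink_window_ms` of a blink, (3) fixations outside
#' the duration bounds, (4) trials with total blink time at or above
#' `max_trial_blink_ms`. Every removed fixation/saccade is retained in a
#' quarantine table with its removal reason, so
#' `kept + removed = input` at every stage.
#'
#' Stage percentages are computed against the pre-cleaning count of
#' fixations plus saccades; the trial-exclusion percentage is against the
#' trial count; the total is the sum of stage percentages (the convention
#' under which the four stages of a typical free-viewing data set add up
#' to the overall exclusion figure).
#'
#' @param events Event table including blink rows (blinks are the cleaning
#'   reference, not its target).
#' @param params A [cleaning_params()].
#' @return A list of class `cleaning_result`:
#'   * `events` — cleaned event table (blink rows of retained trials kept),
#'   * `quarantine` — removed fixation/saccade rows with a `reason` column,
#'   * `excluded_trials` — tibble of excluded trials with total blink time,
#'   * `report` — per-stage tibble of removal counts and percentages.
#' @export
clean_events <- function(events, params = cleaning_params()) {
  validate_event_table(events)
  blinks <- events[events$event_kind == "blink", ]
  work <- events[events$event_kind != "blink", ]
  n_input <- nrow(work)
  trials <- dplyr::distinct(events, .data$participant_id, .data$trial_index)
  n_trials <- nrow(trials)

  quarantine <- work[0, ]
  quarantine$reason <- character()
  stage_rows <- list()
  note <- function(stage, removed, trials_removed = 0L) {
    stage_rows[[length(stage_rows) + 1]] <<- tibble::tibble(
      stage = stage,
      fixations_removed = sum(removed$event_kind == "fixation"),
      saccades_removed = sum(removed$event_kind == "saccade"),
      trials_removed = trials_removed,
      pct = if (stage == "trial_blink") {
        if (n_trials > 0) 100 * trials_removed / n_trials else 0
      } else {
        if (n_input > 0) 100 * nrow(removed) / n_input else 0
      }
    )
    if (nrow(removed)) {
      removed$reason <- stage
      quarantine <<- dplyr::bind_rows(quarantine, removed)
    }
  }

  s1 <- drop_pre_onset(work, params$trial_onset_ms)
  note("pre_onset", s1$removed)
  s2 <- drop_blink_adjacent(s1$kept, blinks, params$blink_window_ms)
  note("blink_adjacent", s2$removed)
  s3 <- filter_fix_duration(s2$kept, params$min_fix_ms, params$max_fix_ms)
  note("fix_duration", s3$removed)
  combined <- dplyr::bind_rows(s3$kept, blinks)
  s4 <- exclude_trials(combined, params$max_trial_blink_ms)
  note("trial_blink", s4$removed[s4$removed$event_kind != "blink", ],
       trials_removed = nrow(s4$excluded_trials))

  report <- dplyr::bind_rows(stage_rows)
  cleaned <- dplyr::arrange(s4$kept, .data$participant_id,
                            .data$trial_index, .data$onset_ms)
  structure(
    list(events = cleaned, quarantine = quarantine,
         excluded_trials = s4$excluded_trials, report = report,
         n_input_events = n_input, n_input_trials = n_trials,
         total_pct = sum(report$pct)),
    class = "cleaning_result"
  )
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat(sprintf("<cleaning_result> %d events in, %d kept (%.1f%% excluded)\n",
              x$n_input_events,
              sum(x$events$event_kind != "blink"), x$total_pct))
  print(x$report)
  invisible(x)
}
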