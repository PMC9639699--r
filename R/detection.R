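#' Saccade detection parameters
#'
#' Thresholds of the velocity/acceleration event parser. Defaults follow
#' the EyeLink-style online parser: a saccade starts when gaze speed
#' exceeds 30 deg/s or absolute acceleration exceeds 8000 deg/s^2,
#' sustained for at least 4 ms, and the completed candidate is kept only
#' if its start-to-end deflection exceeds 0.1 deg.
#'
#' @param min_deflection_deg Minimum start-to-end angular deflection, deg.
#' @param min_velocity_deg_s Speed threshold, deg/s.
#' @param min_accel_deg_s2 Absolute acceleration threshold, deg/s^2.
#' @param min_sustain_ms Minimum time the onset criterion must hold, ms.
#' @param velocity_smooth_ms Width of the boxcar applied to positions
#'   before differentiation, ms (rounded to an odd number of samples).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_deflection_deg = 0.1,
                             min_velocity_deg_s = 30,
                             min_accel_deg_s2 = 8000,
                             min_sustain_ms = 4,
                             velocity_smooth_ms = 3) {
  vals <- c(min_deflection_deg, min_velocity_deg_s, min_accel_deg_s2,
            min_sustain_ms, velocity_smooth_ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all detection parameters must be strictly positive", call. = FALSE)
  }
  structure(list(min_deflection_deg = min_deflection_deg,
                 min_velocity_deg_s = min_velocity_deg_s,
                 min_accel_deg_s2 = min_accel_deg_s2,
                 min_sustain_ms = min_sustain_ms,
                 velocity_smooth_ms = velocity_smooth_ms),
            class = "detection_params")
}

# pupil missing or zero marks a blink sample (EyeLink convention)
is_blink_sample <- function(pupil) is.na(pupil) | pupil == 0

#' Detect blinks in one trial's sample series
#'
#' Blinks are maximal runs of samples whose pupil signal is missing or
#' zero. Runs separated by at most `merge_gap_ms` are merged; the default
#' 0 performs no merging. Intervals are half-open `[onset, offset)`: the
#' offset is one sample period past the last missing sample.
#'
#' @param samples Tibble with `t_ms` and `pupil` for a single trial,
#'   time-ordered.
#' @param merge_gap_ms Merge blinks separated by gaps of at most this
#'   many milliseconds.
#' @param sample_period_ms Sample spacing, ms (1 at 1000 Hz).
#' @return Tibble with `onset_ms`, `offset_ms`, time-ordered and
#'   non-overlapping; zero rows if the pupil signal is always present.
#' @export
detect_blinks <- function(samples, merge_gap_ms = 0, sample_period_ms = 1) {
  miss <- is_blink_sample(samples$pupil)
  if (!any(miss)) {
    return(tibble::tibble(onset_ms = integer(), offset_ms = integer()))
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- samples$t_ms[starts[r$values]]
  off <- samples$t_ms[ends[r$values]] + as.integer(sample_period_ms)
  if (merge_gap_ms > 0 && length(on) > 1) {
    keep_on <- on[1]; keep_off <- off[1]
    res_on <- integer(); res_off <- integer()
    for (i in seq_along(on)[-1]) {
      if (on[i] - keep_off <= merge_gap_ms) {
        keep_off <- max(keep_off, off[i])
      } else {
        res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
        keep_on <- on[i]; keep_off <- off[i]
      }
    }
    on <- c(res_on, keep_on); off <- c(res_off, keep_off)
  }
  tibble::tibble(onset_ms = as.integer(on), offset_ms = as.integer(off))
}

#' Per-sample gaze kinematics
#'
#' Converts pixel positions to degrees, masks samples inside blinks
#' (missing/zero pupil), boxcar-smooths positions over
#' `velocity_smooth_ms`, and differentiates: 2D speed from per-axis
#' central differences, acceleration as the central difference of speed.
#' Endpoints are padded by replication. Samples in or adjacent to blinks
#' yield `NA` kinematics.
#'
#' @param samples One trial's samples, time-ordered, uniformly spaced.
#' @param geometry A [screen_geometry()].
#' @param params A [detection_params()].
#' @return Tibble with `t_ms`, `x_deg`, `y_deg`, `speed_deg_s`,
#'   `accel_deg_s2`.
#' @export
compute_kinematics <- function(samples, geometry = screen_geometry(),
                               params = detection_params()) {
  n <- nrow(samples)
  if (n < 5) stop("need at least 5 samples for kinematics", call. = FALSE)
  dts <- diff(samples$t_ms)
  period <- 1000 / geometry$sample_rate_hz
  if (length(unique(dts)) != 1 || dts[1] != period) {
    stop(sprintf("non-uniform sampling: expected %g ms spacing", period),
         call. = FALSE)
  }
  pos <- px_to_deg(samples$x_px, samples$y_px, geometry)
  x <- pos$x_deg; y <- pos$y_deg
  blink <- is_blink_sample(samples$pupil)
  x[blink] <- NA_real_; y[blink] <- NA_real_

  w <- max(1L, round(params$velocity_smooth_ms * geometry$sample_rate_hz / 1000))
  if (w %% 2 == 0) w <- w + 1L
  xs <- boxcar(x, w); ys <- boxcar(y, w)
  dt_s <- period / 1000
  speed <- sqrt(central_diff(xs, dt_s)^2 + central_diff(ys, dt_s)^2)
  accel <- central_diff(speed, dt_s)
  tibble::tibble(t_ms = samples$t_ms, x_deg = x, y_deg = y,
                 speed_deg_s = speed, accel_deg_s2 = accel)
}

# centered moving average with replicated-endpoint padding; accumulates
# addends in increasing index order
boxcar <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  acc <- xp[seq_len(n)]
  for (o in seq_len(w - 1L)) acc <- acc + xp[(1L + o):(n + o)]
  acc / w
}

# two-point central difference with replicated-endpoint padding
central_diff <- function(x, dt_s) {
  n <- length(x)
  xp <- c(x[1], x, x[n])
  (xp[3:(n + 2)] - xp[1:n]) / (2 * dt_s)
}

#' Detect saccades in one trial's sample series
#'
#' A candidate saccade begins at the first sample where speed exceeds
#' `min_velocity_deg_s` or absolute acceleration exceeds
#' `min_accel_deg_s2`, with that trigger sustained for at least
#' `min_sustain_ms`; it ends at the first subsequent sample where speed
#' and absolute acceleration are both below their thresholds. Candidates
#' are kept only if the start-to-end deflection exceeds
#' `min_deflection_deg`, and discarded if they overlap a blink.
#' Intervals are half-open `[onset, offset)`; the amplitude is measured
#' from the onset sample to the offset (first quiet) sample, i.e. the
#' landing position.
#'
#' @inheritParams compute_kinematics
#' @param blinks Blink intervals from [detect_blinks()]; detected from the
#'   pupil signal when `NULL`.
#' @return Tibble of saccades with onset/offset/duration, start and end
#'   positions (px and deg), `amplitude_deg` and `peak_velocity_deg_s`;
#'   zero rows when nothing crosses threshold.
#' @export
detect_saccades <- function(samples, geometry = screen_geometry(),
                            params = detection_params(), blinks = NULL) {
  if (is.null(blinks)) blinks <- detect_blinks(samples)
  kin <- compute_kinematics(samples, geometry, params)
  n <- nrow(kin)
  period <- 1000 / geometry$sample_rate_hz
  sus <- as.integer(ceiling(params$min_sustain_ms * geometry$sample_rate_hz / 1000))

  v <- kin$speed_deg_s; a <- abs(kin$accel_deg_s2)
  trig <- (v > params$min_velocity_deg_s) | (a > params$min_accel_deg_s2)
  trig[is.na(trig)] <- FALSE
  # NA kinematics (blinks, their smoothing margins) neither trigger nor
  # terminate: a candidate running into a blink spans it and is discarded
  quiet <- (v < params$min_velocity_deg_s) & (a < params$min_accel_deg_s2)
  quiet[is.na(quiet)] <- FALSE

  r <- rle(trig)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  cand <- which(r$values & r$lengths >= sus)

  empty <- tibble::tibble(
    onset_ms = integer(), offset_ms = integer(), duration_ms = integer(),
    x_start_px = double(), y_start_px = double(),
    x_end_px = double(), y_end_px = double(),
    x_start_deg = double(), y_start_deg = double(),
    x_end_deg = double(), y_end_deg = double(),
    amplitude_deg = double(), peak_velocity_deg_s = double()
  )
  if (!length(cand)) return(empty)

  out <- vector("list", length(cand))
  n_out <- 0L
  scan_from <- 1L
  for (ci in cand) {
    i <- run_start[ci]
    if (i < scan_from) next  # swallowed by a previous saccade
    k_rel <- which(quiet[(i + 1L):n])
    k <- if (length(k_rel)) i + k_rel[1] else n + 1L
    onset_ms <- kin$t_ms[i]
    offset_ms <- if (k <= n) kin$t_ms[k] else kin$t_ms[n] + as.integer(period)
    endi <- min(k, n)
    amp <- angular_distance(kin$x_deg[i], kin$y_deg[i],
                            kin$x_deg[endi], kin$y_deg[endi])
    scan_from <- k + 1L
    if (is.na(amp) || amp <= params$min_deflection_deg) next
    if (overlaps_any(onset_ms, offset_ms, blinks)) next
    n_out <- n_out + 1L
    out[[n_out]] <- tibble::tibble(
      onset_ms = onset_ms, offset_ms = offset_ms,
      duration_ms = offset_ms - onset_ms,
      x_start_px = samples$x_px[i], y_start_px = samples$y_px[i],
      x_end_px = samples$x_px[endi], y_end_px = samples$y_px[endi],
      x_start_deg = kin$x_deg[i], y_start_deg = kin$y_deg[i],
      x_end_deg = kin$x_deg[endi], y_end_deg = kin$y_deg[endi],
      amplitude_deg = amp,
      peak_velocity_deg_s = max(v[i:(max(i, k - 1L))], na.rm = TRUE)
    )
  }
  if (!n_out) return(empty)
  dplyr::bind_rows(out[seq_len(n_out)])
}

overlaps_any <- function(onset, offset, intervals) {
  if (nrow(intervals) == 0) return(FALSE)
  any(onset < intervals$offset_ms & intervals$onset_ms < offset)
}

#' Segment fixations as the complement of saccades and blinks
#'
#' Maximal intervals of `[0, trial_duration_ms)` not covered by a saccade
#' or blink become fixations, so fixations, saccades and blinks partition
#' the trial. The centroid is the mean sample position over the interval;
#' `preceding_saccade_amplitude_deg` is set from the immediately
#' preceding saccade only if that saccade's offset abuts the fixation's
#' onset.
#'
#' @param samples One trial's samples (for centroids), time-ordered.
#' @param saccades,blinks Time-ordered, non-overlapping interval tibbles.
#' @param trial_duration_ms Trial length; defaults to one sample period
#'   past the last sample.
#' @param geometry A [screen_geometry()].
#' @return Tibble of fixations with onset/offset/duration, centroid in px
#'   and deg, and `preceding_saccade_amplitude_deg` (`NA` when the
#'   fixation does not directly follow a saccade).
#' @export
segment_fixations <- function(samples, saccades, blinks,
                              trial_duration_ms = NULL,
                              geometry = screen_geometry()) {
  period <- 1000 / geometry$sample_rate_hz
  if (is.null(trial_duration_ms)) {
    trial_duration_ms <- max(samples$t_ms) + period
  }
  occ <- rbind(
    data.frame(onset_ms = saccades$onset_ms, offset_ms = saccades$offset_ms),
    data.frame(onset_ms = blinks$onset_ms, offset_ms = blinks$offset_ms)
  )
  occ <- occ[order(occ$onset_ms), , drop = FALSE]
  if (nrow(occ) > 1 &&
      any(occ$onset_ms[-1] < occ$offset_ms[-nrow(occ)])) {
    stop("overlapping saccade/blink intervals", call. = FALSE)
  }
  bounds_on <- c(0, occ$offset_ms)
  bounds_off <- c(occ$onset_ms, trial_duration_ms)
  keep <- bounds_off > bounds_on
  fix_on <- bounds_on[keep]; fix_off <- bounds_off[keep]
  if (!length(fix_on)) {
    return(tibble::tibble(
      onset_ms = integer(), offset_ms = integer(), duration_ms = integer(),
      x_px = double(), y_px = double(), x_deg = double(), y_deg = double(),
      preceding_saccade_amplitude_deg = double()
    ))
  }
  cx <- cy <- numeric(length(fix_on))
  for (i in seq_along(fix_on)) {
    in_fix <- samples$t_ms >= fix_on[i] & samples$t_ms < fix_off[i]
    cx[i] <- mean(samples$x_px[in_fix], na.rm = TRUE)
    cy[i] <- mean(samples$y_px[in_fix], na.rm = TRUE)
  }
  pos <- px_to_deg(cx, cy, geometry)
  prec <- vapply(fix_on, function(on) {
    hit <- which(saccades$offset_ms == on)
    if (length(hit)) saccades$amplitude_deg[hit[1]] else NA_real_
  }, numeric(1))
  tibble::tibble(
    onset_ms = as.integer(fix_on), offset_ms = as.integer(fix_off),
    duration_ms = as.integer(fix_off - fix_on),
    x_px = cx, y_px = cy, x_deg = pos$x_deg, y_deg = pos$y_deg,
    preceding_saccade_amplitude_deg = prec
  )
}

#' Detect all events across a multi-trial sample table
#'
#' Runs blink detection, saccade detection and fixation segmentation on
#' every `(participant_id, trial_index)` group of a samples tibble and
#' returns one combined event table.
#'
#' @param samples Samples tibble as from [read_gaze_samples()] or
#'   [simulate_dataset()].
#' @param geometry A [screen_geometry()].
#' @param params A [detection_params()].
#' @param merge_gap_ms Blink merge gap, ms (see [detect_blinks()]).
#' @param trial_duration_ms Trial length for fixation segmentation;
#'   `NULL` infers it per trial from the last sample.
#' @return An event table (see [event_table()]) covering all trials.
#' @export
detect_events <- function(samples, geometry = screen_geometry(),
                          params = detection_params(), merge_gap_ms = 0,
                          trial_duration_ms = NULL) {
  groups <- dplyr::group_split(
    dplyr::group_by(samples, .data$participant_id, .data$trial_index)
  )
  out <- purrr::map(groups, function(tr) {
    blinks <- detect_blinks(tr, merge_gap_ms,
                            1000 / geometry$sample_rate_hz)
    sacc <- detect_saccades(tr, geometry, params, blinks)
    fix <- segment_fixations(tr, sacc, blinks, trial_duration_ms, geometry)
    pid <- tr$participant_id[1]; ti <- tr$trial_index[1]
    dplyr::bind_rows(
      event_table(pid, ti, "fixation", fix$onset_ms, fix$offset_ms,
                  fix$x_px, fix$y_px, fix$x_px, fix$y_px),
      event_table(pid, ti, "saccade", sacc$onset_ms, sacc$offset_ms,
                  sacc$x_start_px, sacc$y_start_px,
                  sacc$x_end_px, sacc$y_end_px, sacc$amplitude_deg),
      event_table(pid, ti, "blink", blinks$onset_ms, blinks$offset_ms)
    )
  })
  ev <- dplyr::bind_rows(out)
  dplyr::arrange(ev, .data$participant_id, .data$trial_index, .data$onset_ms)
}
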