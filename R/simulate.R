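#' Simulation configuration for synthetic scanpaths
#'
#' Generative parameters of the synthetic free-viewing scanpath model.
#' Each condition carries an asymptote/acceleration pair for mean
#' fixation duration (`b_fd` ms, `a_fd` s) and for median saccade
#' amplitude (`b_sa` deg, `a_sa` s); the generator's mean-duration curve
#' is `b_fd * exp(a_fd / t)` clocked by the fixation's start time
#' (floored at `clock_floor_s` to avoid the t -> 0 singularity).
#' Fixation durations are Gamma with shape `fd_shape`; saccade
#' amplitudes are log-normal with log-sd `sa_sigma_log`, constrained by
#' the condition's gaze-contingent mask (within 5 degrees of gaze for
#' the central window, beyond it for the peripheral scotoma). Blinks
#' arrive as a Poisson process; Gaussian positional noise of sd
#' `noise_sd_deg` is added to fixation samples.
#'
#' Condition asymptote defaults equal the fitted values typical of this
#' paradigm (fixation duration 283.5/311.4/321.2 ms and saccade
#' amplitude 3.5/8.1/5.4 deg for central/peripheral/control);
#' acceleration defaults are chosen so the curves approach asymptote
#' between roughly 3.5 and 6 s of viewing.
#'
#' @param conditions Named list (central/peripheral/control) of lists
#'   with `b_fd`, `a_fd`, `b_sa`, `a_sa`.
#' @param fd_shape Gamma shape of fixation durations (dimensionless).
#' @param sa_sigma_log Log-sd of saccade amplitudes.
#' @param noise_sd_deg Positional noise sd on fixation samples, degrees.
#' @param blink_rate_per_s Poisson blink rate.
#' @param blink_dur_mean_ms Mean blink duration, ms.
#' @param n_participants,trials_per_condition Design size (the full
#'   design is `n_participants x 3 x trials_per_condition` trials).
#' @param trial_ms Trial duration, ms.
#' @param sample_rate_hz Sampling rate of rendered gaze streams.
#' @param mask_radius_deg Gaze-contingent mask radius, degrees.
#' @param clock_floor_s Floor applied to the curve clock, seconds.
#' @param seed Integer master seed; per-trial child seeds are derived
#'   from it, so outputs are fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(
    conditions = list(
      central = list(b_fd = 283.5, a_fd = -0.15, b_sa = 3.5, a_sa = 0.3),
      peripheral = list(b_fd = 311.4, a_fd = -0.25, b_sa = 8.1, a_sa = 0.4),
      control = list(b_fd = 321.2, a_fd = -0.23, b_sa = 5.4, a_sa = 0.4)
    ),
    fd_shape = 6, sa_sigma_log = 0.35, noise_sd_deg = 0.03,
    blink_rate_per_s = 0.12, blink_dur_mean_ms = 150,
    n_participants = 42, trials_per_condition = 30,
    trial_ms = 20000, sample_rate_hz = 1000,
    mask_radius_deg = 5, clock_floor_s = 0.25, seed = 1) {
  stopifnot(setequal(names(conditions), CONDITIONS),
            fd_shape > 0, sa_sigma_log > 0, noise_sd_deg >= 0,
            blink_rate_per_s >= 0, blink_dur_mean_ms > 0,
            n_participants >= 1, trials_per_condition >= 1, trial_ms > 0)
  structure(
    list(conditions = conditions, fd_shape = fd_shape,
         sa_sigma_log = sa_sigma_log, noise_sd_deg = noise_sd_deg,
         blink_rate_per_s = blink_rate_per_s,
         blink_dur_mean_ms = blink_dur_mean_ms,
         n_participants = n_participants,
         trials_per_condition = trials_per_condition,
         trial_ms = as.integer(trial_ms), sample_rate_hz = sample_rate_hz,
         mask_radius_deg = mask_radius_deg, clock_floor_s = clock_floor_s,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Asymptotic realized mean saccade amplitude of the generator
#'
#' The generator draws saccade amplitudes from a log-normal whose
#' *median* follows the condition curve, truncated by the condition's
#' mask (amplitudes at most the mask radius under the central window,
#' above it under the peripheral scotoma). The asymptote of the realized
#' *mean* amplitude therefore differs from `b_sa`; this helper returns
#' it in closed form (truncated log-normal mean with median `b_sa`),
#' which is the quantity a time-course fit of binned mean amplitudes
#' estimates.
#'
#' @param cfg A [sim_config()].
#' @param condition Condition name.
#' @return Expected realized mean amplitude at asymptote, degrees.
#' @export
sim_amplitude_asymptote <- function(cfg, condition) {
  cp <- cfg$conditions[[condition]]
  mu <- log(cp$b_sa); s <- cfg$sa_sigma_log
  full <- exp(mu + s^2 / 2)
  r <- cfg$mask_radius_deg
  z <- (log(r) - mu) / s
  switch(condition,
    control = full,
    central = full * stats::pnorm(z - s) / stats::pnorm(z),
    peripheral = full * (1 - stats::pnorm(z - s)) / (1 - stats::pnorm(z))
  )
}

# One trial's event schedule in degree space, blinks carved out.
# Returns plain lists for speed; used by simulate_trial/simulate_dataset.
sim_trial_core <- function(cfg, condition) {
  cp <- cfg$conditions[[condition]]
  geom <- screen_geometry(sample_rate_hz = cfg$sample_rate_hz)
  hw <- geom$half_width_deg; hh <- geom$half_height_deg
  r <- cfg$mask_radius_deg
  trial_ms <- cfg$trial_ms
  rgamma <- stats::rgamma; rlnorm <- stats::rlnorm; runif <- stats::runif
  mode_win <- condition == "central"; mode_sco <- condition == "peripheral"

  cap <- ceiling(trial_ms / 40) + 8L
  f_on <- f_off <- integer(cap); f_x <- f_y <- numeric(cap)
  s_on <- s_off <- integer(cap)
  s_x0 <- s_y0 <- s_x1 <- s_y1 <- s_amp <- numeric(cap)
  nf <- ns <- 0L
  gx <- 0; gy <- 0
  t <- 0L

  repeat {
    clock <- max(t / 1000, cfg$clock_floor_s)
    mean_fd <- cp$b_fd * exp(cp$a_fd / clock)
    dur <- max(10L, as.integer(round(rgamma(
      1, shape = cfg$fd_shape, scale = mean_fd / cfg$fd_shape))))
    nf <- nf + 1L
    f_on[nf] <- t; f_x[nf] <- gx; f_y[nf] <- gy
    if (t + dur >= trial_ms) { f_off[nf] <- trial_ms; break }
    f_off[nf] <- t + dur
    t <- t + dur

    clock <- max(t / 1000, cfg$clock_floor_s)
    med <- cp$b_sa * exp(cp$a_sa / clock)
    amp <- NA_real_
    for (j in 1:100) {
      a_try <- rlnorm(1, log(med), cfg$sa_sigma_log)
      ok <- if (mode_win) a_try <= r else if (mode_sco) a_try > r else TRUE
      amp <- a_try
      if (ok) break
    }
    ex <- ey <- NA_real_
    found <- FALSE
    for (j in 1:100) {
      th <- runif(1, 0, 2 * pi)
      cx <- gx + amp * cos(th); cy <- gy + amp * sin(th)
      if (abs(cx) <= hw && abs(cy) <= hh) { ex <- cx; ey <- cy; found <- TRUE; break }
    }
    if (!found) {
      # clip the amplitude along the last direction to stay on screen
      dx <- cos(th); dy <- sin(th)
      sx <- if (dx > 0) (hw - gx) / dx else if (dx < 0) (-hw - gx) / dx else Inf
      sy <- if (dy > 0) (hh - gy) / dy else if (dy < 0) (-hh - gy) / dy else Inf
      amp <- 0.95 * min(sx, sy, amp)
      ex <- gx + amp * dx; ey <- gy + amp * dy
    }
    dur_s <- max(4L, as.integer(round(min(21 + 2.2 * amp, 44 * amp))))
    if (t + dur_s >= trial_ms) { f_off[nf] <- trial_ms; break }
    ns <- ns + 1L
    s_on[ns] <- t; s_off[ns] <- t + dur_s
    s_x0[ns] <- gx; s_y0[ns] <- gy; s_x1[ns] <- ex; s_y1[ns] <- ey
    s_amp[ns] <- angular_distance(gx, gy, ex, ey)
    t <- t + dur_s
    gx <- ex; gy <- ey
  }

  fix <- list(on = f_on[seq_len(nf)], off = f_off[seq_len(nf)],
              x = f_x[seq_len(nf)], y = f_y[seq_len(nf)])
  sac <- list(on = s_on[seq_len(ns)], off = s_off[seq_len(ns)],
              x0 = s_x0[seq_len(ns)], y0 = s_y0[seq_len(ns)],
              x1 = s_x1[seq_len(ns)], y1 = s_y1[seq_len(ns)],
              amp = s_amp[seq_len(ns)])

  # Poisson blinks, merged, then carved out of the schedule so the
  # ground-truth events still partition the trial
  nb <- stats::rpois(1, cfg$blink_rate_per_s * trial_ms / 1000)
  if (nb > 0) {
    b_on <- sort(as.integer(floor(stats::runif(nb, 0, trial_ms))))
    b_dur <- pmax(20L, as.integer(round(stats::rgamma(
      nb, shape = 4, scale = cfg$blink_dur_mean_ms / 4))))
    b_off <- pmin(b_on + b_dur, trial_ms)
    keep <- b_off > b_on
    b <- merge_sorted_intervals(b_on[keep], b_off[keep])
    fix[c("on", "off", "x", "y")] <-
      carve_events(fix$on, fix$off, b$on, b$off,
                   list(fix$x, fix$y)) |> unname()
    sac[c("on", "off", "x0", "y0", "x1", "y1", "amp")] <-
      carve_events(sac$on, sac$off, b$on, b$off,
                   list(sac$x0, sac$y0, sac$x1, sac$y1, sac$amp)) |> unname()
    blinks <- list(on = b$on, off = b$off)
  } else {
    blinks <- list(on = integer(), off = integer())
  }
  list(fix = fix, sac = sac, blinks = blinks, schedule = list(
    fix_on = f_on[seq_len(nf)], fix_off = f_off[seq_len(nf)],
    fix_x = f_x[seq_len(nf)], fix_y = f_y[seq_len(nf)],
    sac_on = s_on[seq_len(ns)], sac_off = s_off[seq_len(ns)],
    sac_x0 = s_x0[seq_len(ns)], sac_y0 = s_y0[seq_len(ns)],
    sac_x1 = s_x1[seq_len(ns)], sac_y1 = s_y1[seq_len(ns)]
  ))
}

merge_sorted_intervals <- function(on, off) {
  if (length(on) <= 1) return(list(on = on, off = off))
  ro <- integer(); rf <- integer()
  co <- on[1]; cf <- off[1]
  for (i in 2:length(on)) {
    if (on[i] <= cf) cf <- max(cf, off[i]) else {
      ro <- c(ro, co); rf <- c(rf, cf); co <- on[i]; cf <- off[i]
    }
  }
  list(on = c(ro, co), off = c(rf, cf))
}

# subtract blink intervals from events, splitting where needed; attrs is
# a list of per-event attribute vectors copied onto each piece
carve_events <- function(on, off, b_on, b_off, attrs) {
  if (!length(b_on) || !length(on)) {
    return(c(list(on, off), attrs))
  }
  out_on <- integer(); out_off <- integer()
  out_attrs <- lapply(attrs, function(a) a[0])
  for (i in seq_along(on)) {
    segs_on <- on[i]; segs_off <- off[i]
    for (j in seq_along(b_on)) {
      new_on <- integer(); new_off <- integer()
      for (k in seq_along(segs_on)) {
        if (b_off[j] <= segs_on[k] || b_on[j] >= segs_off[k]) {
          new_on <- c(new_on, segs_on[k]); new_off <- c(new_off, segs_off[k])
        } else {
          if (b_on[j] > segs_on[k]) {
            new_on <- c(new_on, segs_on[k]); new_off <- c(new_off, b_on[j])
          }
          if (b_off[j] < segs_off[k]) {
            new_on <- c(new_on, b_off[j]); new_off <- c(new_off, segs_off[k])
          }
        }
      }
      segs_on <- new_on; segs_off <- new_off
    }
    if (length(segs_on)) {
      out_on <- c(out_on, segs_on); out_off <- c(out_off, segs_off)
      for (m in seq_along(attrs)) {
        out_attrs[[m]] <- c(out_attrs[[m]], rep(attrs[[m]][i],
                                                length(segs_on)))
      }
    }
  }
  c(list(out_on, out_off), out_attrs)
}

core_to_truth <- function(core, pid, trial, geom) {
  fpx <- deg_to_px(core$fix$x, core$fix$y, geom)
  s0 <- deg_to_px(core$sac$x0, core$sac$y0, geom)
  s1 <- deg_to_px(core$sac$x1, core$sac$y1, geom)
  dplyr::bind_rows(
    event_table(pid, trial, "fixation", core$fix$on, core$fix$off,
                fpx$x_px, fpx$y_px, fpx$x_px, fpx$y_px),
    event_table(pid, trial, "saccade", core$sac$on, core$sac$off,
                s0$x_px, s0$y_px, s1$x_px, s1$y_px, core$sac$amp),
    event_table(pid, trial, "blink", core$blinks$on, core$blinks$off)
  ) |> dplyr::arrange(.data$onset_ms)
}

render_core <- function(core, cfg, geom) {
  n <- cfg$trial_ms
  x <- numeric(n); y <- numeric(n)
  sch <- core$schedule
  for (i in seq_along(sch$fix_on)) {
    idx <- (sch$fix_on[i] + 1L):sch$fix_off[i]
    x[idx] <- sch$fix_x[i] + stats::rnorm(length(idx), 0, cfg$noise_sd_deg)
    y[idx] <- sch$fix_y[i] + stats::rnorm(length(idx), 0, cfg$noise_sd_deg)
  }
  for (i in seq_along(sch$sac_on)) {
    d <- sch$sac_off[i] - sch$sac_on[i]
    u <- (0:(d - 1L)) / d
    f <- u - sin(2 * pi * u) / (2 * pi)  # raised-cosine speed profile
    idx <- (sch$sac_on[i] + 1L):sch$sac_off[i]
    x[idx] <- sch$sac_x0[i] + f * (sch$sac_x1[i] - sch$sac_x0[i])
    y[idx] <- sch$sac_y0[i] + f * (sch$sac_y1[i] - sch$sac_y0[i])
  }
  pupil <- rep(1000, n)
  for (i in seq_along(core$blinks$on)) {
    idx <- (core$blinks$on[i] + 1L):core$blinks$off[i]
    pupil[idx] <- 0
    x[idx] <- NA_real_; y[idx] <- NA_real_
  }
  px <- deg_to_px(x, y, geom)
  tibble::tibble(t_ms = 0:(n - 1L), x_px = px$x_px, y_px = px$y_px,
                 pupil = pupil)
}

#' Simulate a single trial
#'
#' Generates one trial's alternating fixation-saccade scanpath with
#' ground-truth events and (optionally) the rendered 1000 Hz gaze
#' stream. Saccade trajectories follow a raised-cosine speed profile
#' whose peak always exceeds the 30 deg/s detection threshold for
#' amplitudes of at least 0.3 deg; blinks zero the pupil and mask
#' position.
#'
#' @param cfg A [sim_config()].
#' @param condition `"central"`, `"peripheral"` or `"control"`.
#' @param seed Optional integer seed for this trial.
#' @param participant_id,trial_index Identifiers stamped onto the output.
#' @param render_samples If `FALSE`, skip sample rendering and return
#'   `samples = NULL` (the ground truth is identical either way, since
#'   the schedule and blink random draws precede rendering noise).
#' @return `list(samples, truth)`: a samples tibble (with trial metadata
#'   columns) and a ground-truth event table.
#' @export
simulate_trial <- function(cfg, condition, seed = NULL,
                           participant_id = "p01", trial_index = 1L,
                           render_samples = TRUE) {
  condition <- match.arg(condition, CONDITIONS)
  if (!is.null(seed)) set.seed(seed)
  geom <- screen_geometry(sample_rate_hz = cfg$sample_rate_hz)
  core <- sim_trial_core(cfg, condition)
  truth <- core_to_truth(core, participant_id, trial_index, geom)
  samples <- NULL
  if (render_samples) {
    samples <- render_core(core, cfg, geom)
    samples <- tibble::tibble(
      participant_id = participant_id, trial_index = as.integer(trial_index),
      condition = condition, scene_type = NA_character_, samples
    )
  }
  list(samples = samples, truth = truth)
}

#' Simulate a full experiment dataset
#'
#' Emulates the full design: `n_participants` participants x 3 visual
#' conditions x `trials_per_condition` trials each, with scene types
#' alternating natural/urban within each condition. Each trial runs on a
#' child seed derived from `cfg$seed`, so the dataset is reproducible
#' and individual trials can be regenerated in isolation.
#'
#' @param cfg A [sim_config()].
#' @param render_samples If `TRUE`, also render the 1000 Hz gaze streams
#'   (one 20-s trial is 20,000 samples; the full default design is large,
#'   so rendering is off by default and the ground-truth event store is
#'   returned for event-level analyses).
#' @return `list(samples, truth, manifest)`: samples tibble or `NULL`,
#'   ground-truth event table for every trial, and the trial manifest.
#' @export
simulate_dataset <- function(cfg = sim_config(), render_samples = FALSE) {
  geom <- screen_geometry(sample_rate_hz = cfg$sample_rate_hz)
  pids <- sprintf("p%02d", seq_len(cfg$n_participants))
  tpc <- cfg$trials_per_condition
  manifest <- tidyr::expand_grid(participant_id = pids,
                                 slot = seq_len(3 * tpc)) |>
    dplyr::mutate(
      trial_index = .data$slot,
      condition = rep(rep(CONDITIONS, each = tpc), times = cfg$n_participants),
      scene_type = rep(rep(SCENE_TYPES, length.out = tpc),
                       times = 3 * cfg$n_participants),
      scene_id = sprintf("scene_%03d", .data$slot)
    ) |>
    dplyr::select(dplyr::all_of(MANIFEST_HEADER))

  n_tr <- nrow(manifest)
  acc <- list(pid = vector("list", n_tr), ti = vector("list", n_tr),
              kind = vector("list", n_tr), on = vector("list", n_tr),
              off = vector("list", n_tr), x0 = vector("list", n_tr),
              y0 = vector("list", n_tr), x1 = vector("list", n_tr),
              y1 = vector("list", n_tr), amp = vector("list", n_tr))
  sample_list <- if (render_samples) vector("list", n_tr) else NULL
  for (i in seq_len(n_tr)) {
    set.seed(child_seed(cfg$seed, i))
    core <- sim_trial_core(cfg, manifest$condition[i])
    nf <- length(core$fix$on); ns <- length(core$sac$on)
    nb <- length(core$blinks$on)
    fpx <- deg_to_px(core$fix$x, core$fix$y, geom)
    s0 <- deg_to_px(core$sac$x0, core$sac$y0, geom)
    s1 <- deg_to_px(core$sac$x1, core$sac$y1, geom)
    acc$pid[[i]] <- rep(manifest$participant_id[i], nf + ns + nb)
    acc$ti[[i]] <- rep(manifest$trial_index[i], nf + ns + nb)
    acc$kind[[i]] <- rep(c("fixation", "saccade", "blink"), c(nf, ns, nb))
    acc$on[[i]] <- c(core$fix$on, core$sac$on, core$blinks$on)
    acc$off[[i]] <- c(core$fix$off, core$sac$off, core$blinks$off)
    acc$x0[[i]] <- c(fpx$x_px, s0$x_px, rep(NA_real_, nb))
    acc$y0[[i]] <- c(fpx$y_px, s0$y_px, rep(NA_real_, nb))
    acc$x1[[i]] <- c(fpx$x_px, s1$x_px, rep(NA_real_, nb))
    acc$y1[[i]] <- c(fpx$y_px, s1$y_px, rep(NA_real_, nb))
    acc$amp[[i]] <- c(rep(NA_real_, nf), core$sac$amp, rep(NA_real_, nb))
    if (render_samples) {
      smp <- render_core(core, cfg, geom)
      sample_list[[i]] <- tibble::tibble(
        participant_id = manifest$participant_id[i],
        trial_index = manifest$trial_index[i],
        condition = manifest$condition[i],
        scene_type = manifest$scene_type[i],
        smp
      )
    }
  }
  truth <- event_table(
    unlist(acc$pid), unlist(acc$ti), unlist(acc$kind),
    unlist(acc$on), unlist(acc$off),
    unlist(acc$x0), unlist(acc$y0), unlist(acc$x1), unlist(acc$y1),
    unlist(acc$amp)
  )
  truth <- dplyr::arrange(truth, .data$participant_id, .data$trial_index,
                          .data$onset_ms)
  list(
    samples = if (render_samples) dplyr::bind_rows(sample_list) else NULL,
    truth = truth,
    manifest = manifest
  )
}

# deterministic per-trial child seed below 2^31
child_seed <- function(seed, serial) {
  as.integer((as.double(seed) * 48271 + as.double(serial) * 99991) %%
               2147483629)
}

#' Compare detected events against ground truth
#'
#' Greedy onset-ordered matching per trial and event kind: walking both
#' onset-sorted lists, a detected event whose onset lies within `tol_ms`
#' of the current truth event is a hit; truth events passed over are
#' misses, detected events with no truth partner are spurious.
#'
#' @param detected,truth Event tables over the same set of trials.
#' @param tol_ms Onset matching tolerance, ms.
#' @return A list: `hits`, `misses`, `spurious`, `hit_rate`, and
#'   quantile summaries (0, 0.5, 0.9, 1) of absolute onset, offset and
#'   (for saccades) amplitude errors among hits.
#' @export
truth_compare <- function(detected, truth, tol_ms = 2) {
  key <- function(x) unique(paste(x$participant_id, x$trial_index))
  if (!setequal(key(detected), key(truth))) {
    stop("detected and truth cover different trials", call. = FALSE)
  }
  hits <- misses <- spurious <- 0L
  e_on <- e_off <- e_amp <- numeric()
  for (k in key(truth)) {
    for (kind in EVENT_KINDS) {
      tt <- truth[paste(truth$participant_id, truth$trial_index) == k &
                    truth$event_kind == kind, ]
      dd <- detected[paste(detected$participant_id,
                           detected$trial_index) == k &
                       detected$event_kind == kind, ]
      tt <- tt[order(tt$onset_ms), ]; dd <- dd[order(dd$onset_ms), ]
      i <- j <- 1L
      while (i <= nrow(tt) && j <= nrow(dd)) {
        diff_on <- dd$onset_ms[j] - tt$onset_ms[i]
        if (abs(diff_on) <= tol_ms) {
          hits <- hits + 1L
          e_on <- c(e_on, abs(diff_on))
          e_off <- c(e_off, abs(dd$offset_ms[j] - tt$offset_ms[i]))
          if (kind == "saccade") {
            e_amp <- c(e_amp, abs(dd$amplitude_deg[j] - tt$amplitude_deg[i]))
          }
          i <- i + 1L; j <- j + 1L
        } else if (diff_on < -tol_ms) {
          spurious <- spurious + 1L; j <- j + 1L
        } else {
          misses <- misses + 1L; i <- i + 1L
        }
      }
      misses <- misses + (nrow(tt) - i + 1L)
      spurious <- spurious + (nrow(dd) - j + 1L)
    }
  }
  qs <- function(x) if (length(x)) stats::quantile(x, c(0, 0.5, 0.9, 1)) else
    NULL
  list(hits = hits, misses = misses, spurious = spurious,
       hit_rate = if (hits + misses > 0) hits / (hits + misses) else NA_real_,
       onset_error_q = qs(e_on), offset_error_q = qs(e_off),
       amplitude_error_q = qs(e_amp))
}
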