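# Naive per-sample reference detector: exhaustively scans every sample
# against the three thresholds. Deliberately written as plain loops,
# independent of the package's run-length implementation.
oracle_detect_saccades <- function(samples, geometry = screen_geometry(),
                                   params = detection_params(),
                                   blinks = NULL) {
  n <- nrow(samples)
  period <- 1000 / geometry$sample_rate_hz
  hw <- geometry$width_px / 2
  hh <- geometry$height_px / 2
  x <- (samples$x_px - hw) * geometry$half_width_deg / hw
  y <- (samples$y_px - hh) * geometry$half_height_deg / hh
  blink_smp <- is.na(samples$pupil) | samples$pupil == 0
  x[blink_smp] <- NA_real_
  y[blink_smp] <- NA_real_
  if (is.null(blinks)) {
    blinks <- detect_blinks(samples, 0, period)
  }

  w <- round(params$velocity_smooth_ms * geometry$sample_rate_hz / 1000)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) %/% 2
  pad <- function(v, k) c(rep(v[1], k), v, rep(v[n], k))
  smooth1 <- function(v) {
    vp <- pad(v, h)
    out <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in (i):(i + 2 * h)) s <- s + vp[j]
      out[i] <- s / w
    }
    out
  }
  xs <- if (w > 1) smooth1(x) else x
  ys <- if (w > 1) smooth1(y) else y
  dt <- period / 1000
  cdiff <- function(v) {
    vp <- pad(v, 1)
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- (vp[i + 2] - vp[i]) / (2 * dt)
    out
  }
  speed <- sqrt(cdiff(xs)^2 + cdiff(ys)^2)
  accel <- cdiff(speed)

  vmin <- params$min_velocity_deg_s
  amin <- params$min_accel_deg_s2
  sus <- ceiling(params$min_sustain_ms * geometry$sample_rate_hz / 1000)
  is_trig <- function(i) {
    isTRUE(speed[i] > vmin) || isTRUE(abs(accel[i]) > amin)
  }
  is_quiet <- function(i) {
    if (is.na(speed[i]) || is.na(accel[i])) return(FALSE)
    speed[i] < vmin && abs(accel[i]) < amin
  }

  res <- list()
  i <- 1
  while (i <= n) {
    sustained <- i + sus - 1 <= n
    if (sustained) {
      for (j in i:(i + sus - 1)) if (!is_trig(j)) { sustained <- FALSE; break }
    }
    if (!sustained) { i <- i + 1; next }
    k <- n + 1
    for (j in (i + 1):n) if (is_quiet(j)) { k <- j; break }
    onset_ms <- samples$t_ms[i]
    offset_ms <- if (k <= n) samples$t_ms[k] else samples$t_ms[n] + period
    endi <- min(k, n)
    amp <- sqrt((x[endi] - x[i])^2 + (y[endi] - y[i])^2)
    ok <- !is.na(amp) && amp > params$min_deflection_deg
    if (ok && nrow(blinks) > 0) {
      for (b in seq_len(nrow(blinks))) {
        if (onset_ms < blinks$offset_ms[b] &&
            blinks$onset_ms[b] < offset_ms) { ok <- FALSE; break }
      }
    }
    if (ok) {
      res[[length(res) + 1]] <- data.frame(
        onset_ms = onset_ms, offset_ms = offset_ms, amplitude_deg = amp)
    }
    i <- k + 1
  }
  if (!length(res)) {
    return(data.frame(onset_ms = integer(), offset_ms = integer(),
                      amplitude_deg = double()))
  }
  do.call(rbind, res)
}

# Assorted short gaze streams for detector stress tests: scanpath-model
# trials, random walks with planted jumps, and pure noise.
random_stream <- function(seed, max_ms = 2000) {
  set.seed(seed)
  kind <- seed %% 3
  n <- sample(500:max_ms, 1)
  geom <- screen_geometry()
  if (kind == 0) {
    cfg <- sim_config(trial_ms = n, noise_sd_deg = runif(1, 0, 0.05),
                      blink_rate_per_s = sample(c(0, 0.3), 1))
    tr <- simulate_trial(cfg, sample(c("central", "peripheral", "control"), 1),
                         seed = seed + 1)
    return(tr$samples[, c("t_ms", "x_px", "y_px", "pupil")])
  }
  if (kind == 1) {
    # random walk with occasional step jumps
    x <- cumsum(rnorm(n, 0, 0.01))
    y <- cumsum(rnorm(n, 0, 0.01))
    for (j in seq_len(sample(0:4, 1))) {
      at <- sample(50:(n - 50), 1)
      len <- sample(10:40, 1)
      dx <- runif(1, -6, 6); dy <- runif(1, -4, 4)
      ramp <- seq(0, 1, length.out = len)
      idx <- at:(at + len - 1)
      x[idx] <- x[at] + ramp * dx
      y[idx] <- y[at] + ramp * dy
      if (at + len <= n) {
        x[(at + len):n] <- x[(at + len):n] - x[at + len] + x[at] + dx
        y[(at + len):n] <- y[(at + len):n] - y[at + len] + y[at] + dy
      }
    }
    pupil <- rep(900, n)
    if (runif(1) < 0.3) {
      b <- sample(seq_len(n - 120), 1)
      pupil[b:(b + sample(40:120, 1))] <- 0
    }
  } else {
    x <- rnorm(n, 0, runif(1, 0.02, 0.3))
    y <- rnorm(n, 0, runif(1, 0.02, 0.3))
    pupil <- rep(900, n)
  }
  px <- deg_to_px(x, y, geom)
  tibble::tibble(t_ms = 0:(n - 1), x_px = px$x_px, y_px = px$y_px,
                 pupil = pupil)
}
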