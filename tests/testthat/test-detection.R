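make_stream <- function(x_deg, y_deg = rep(0, length(x_deg)),
                        pupil = rep(1000, length(x_deg)),
                        geom = screen_geometry()) {
  px <- deg_to_px(x_deg, y_deg, geom)
  tibble::tibble(t_ms = seq_along(x_deg) - 1L, x_px = px$x_px,
                 y_px = px$y_px, pupil = pupil)
}

# fixation at 0, linear ramp to `amp` degrees over `ramp_ms`, fixation
planted_saccade <- function(amp = 10, ramp_ms = 20, fix_ms = 500) {
  x <- c(rep(0, fix_ms), amp * seq_len(ramp_ms) / ramp_ms,
         rep(amp, fix_ms))
  make_stream(x)
}

test_that("kinematics are zero at rest, analytic on ramps, isotropic", {
  still <- make_stream(rep(2, 100))
  kin <- compute_kinematics(still)
  expect_true(all(kin$speed_deg_s == 0))
  expect_true(all(kin$accel_deg_s2 == 0))

  # 10 deg over 20 ms: interior slope 500 deg/s
  ramp <- make_stream(c(rep(0, 50), 10 * seq_len(20) / 20, rep(10, 50)))
  kin <- compute_kinematics(ramp)
  expect_equal(kin$speed_deg_s[55:65], rep(500, 11), tolerance = 1e-12)

  horiz <- make_stream(0.05 * (0:99))
  vert <- make_stream(rep(0, 100), 0.05 * (0:99))
  expect_equal(compute_kinematics(horiz)$speed_deg_s,
               compute_kinematics(vert)$speed_deg_s, tolerance = 1e-12)
})

test_that("kinematics require uniform integer-spaced sampling", {
  s <- make_stream(rep(0, 10))
  s$t_ms[5] <- 20L
  expect_error(compute_kinematics(s), "non-uniform")
  expect_error(compute_kinematics(make_stream(rep(0, 4))), "at least 5")
})

test_that("blink detection extracts and merges missing-pupil runs", {
  p <- rep(1000, 200)
  expect_equal(nrow(detect_blinks(make_stream(rep(0, 200), pupil = p))), 0)

  p[51:121] <- 0   # 50..120 ms missing
  b <- detect_blinks(make_stream(rep(0, 200), pupil = p))
  expect_equal(b$onset_ms, 50L)
  expect_equal(b$offset_ms, 121L)

  p2 <- rep(1000, 200)
  p2[51:101] <- NA  # 50-100
  p2[112:151] <- 0  # 111-150, gap 10 ms
  expect_equal(nrow(detect_blinks(make_stream(rep(0, 200), pupil = p2))), 2)
  merged <- detect_blinks(make_stream(rep(0, 200), pupil = p2),
                          merge_gap_ms = 20)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$onset_ms, 50L)
  expect_equal(merged$offset_ms, 151L)
})

test_that("a planted ramp is detected as one saccade with accurate bounds", {
  s <- planted_saccade(10, 20)
  sacc <- detect_saccades(s)
  expect_equal(nrow(sacc), 1)
  # the acceleration trigger plus the 3-ms position smoothing anticipate
  # the kinematic boundary by up to 3 samples
  expect_lte(abs(sacc$onset_ms - 500), 3)
  expect_lte(abs(sacc$offset_ms - 520), 3)
  expect_lt(abs(sacc$amplitude_deg - 10), 0.05)
  expect_gt(sacc$peak_velocity_deg_s, 400)
})

test_that("rest and sub-threshold drift produce no saccades", {
  expect_equal(nrow(detect_saccades(make_stream(rep(1, 500)))), 0)
  # 10 deg of deflection at only 10 deg/s: velocity criterion not met
  drift <- make_stream(0.01 * (0:999))
  expect_equal(nrow(detect_saccades(drift)), 0)
})

test_that("saccades overlapping blinks are discarded", {
  s <- planted_saccade(10, 20)
  s$pupil[505:515] <- 0
  sacc <- detect_saccades(s)
  expect_equal(nrow(sacc), 0)
})

test_that("detector matches the per-sample oracle on varied streams", {
  for (seed in 1:12) {
    s <- random_stream(seed, max_ms = 1200)
    got <- detect_saccades(s)
    want <- oracle_detect_saccades(s)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    expect_identical(got$onset_ms, as.integer(want$onset_ms),
                     info = paste("seed", seed))
    expect_identical(got$offset_ms, as.integer(want$offset_ms),
                     info = paste("seed", seed))
    expect_identical(got$amplitude_deg, want$amplitude_deg,
                     info = paste("seed", seed))
  }
})

test_that("rotating a scanpath by 90 degrees preserves detections", {
  cfg <- sim_config(trial_ms = 2000, noise_sd_deg = 0.02,
                    blink_rate_per_s = 0)
  tr <- simulate_trial(cfg, "control", seed = 42)
  s <- tr$samples
  geom <- screen_geometry()
  d <- px_to_deg(s$x_px, s$y_px, geom)
  rot <- deg_to_px(-d$y_deg, d$x_deg, geom)
  s2 <- s
  s2$x_px <- rot$x_px; s2$y_px <- rot$y_px
  a <- detect_saccades(s)
  b <- detect_saccades(s2)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$onset_ms, b$onset_ms)
  expect_equal(a$amplitude_deg, b$amplitude_deg, tolerance = 1e-9)
})

test_that("a planted 8-degree saccade survives positional noise", {
  clean <- planted_saccade(8, 32, fix_ms = 400)
  base_onset <- detect_saccades(clean)$onset_ms
  for (seed in 1:10) {
    set.seed(seed)
    s <- clean
    d <- px_to_deg(s$x_px, s$y_px, screen_geometry())
    noisy <- deg_to_px(d$x_deg + rnorm(nrow(s), 0, 0.05),
                       d$y_deg + rnorm(nrow(s), 0, 0.05),
                       screen_geometry())
    s$x_px <- noisy$x_px; s$y_px <- noisy$y_px
    sacc <- detect_saccades(s)
    main <- sacc[abs(sacc$amplitude_deg - 8) < 1, ]
    expect_equal(nrow(main), 1, info = paste("seed", seed))
    # noise shifts the detected onset by at most 3 ms relative to the
    # detector's own noise-free boundary convention
    expect_lte(abs(main$onset_ms - base_onset), 3)
  }
})

test_that("fixations complement saccades and blinks and carry amplitudes", {
  s <- make_stream(rep(0, 3000))
  sacc <- tibble::tibble(onset_ms = 1000L, offset_ms = 1030L,
                         amplitude_deg = 6.5)
  none <- tibble::tibble(onset_ms = integer(), offset_ms = integer())
  fix <- segment_fixations(s, sacc, none)
  expect_equal(fix$onset_ms, c(0L, 1030L))
  expect_equal(fix$offset_ms, c(1000L, 3000L))
  expect_equal(fix$preceding_saccade_amplitude_deg, c(NA, 6.5))

  # saccade then blink: the following fixation does not abut the saccade
  blink <- tibble::tibble(onset_ms = 1030L, offset_ms = 1100L)
  fix2 <- segment_fixations(s, sacc, blink)
  expect_true(is.na(fix2$preceding_saccade_amplitude_deg[2]))

  # no events at all: one fixation spanning the trial
  fix3 <- segment_fixations(s, none, none)
  expect_equal(nrow(fix3), 1)
  expect_equal(fix3$duration_ms, 3000L)

  overlapping <- tibble::tibble(onset_ms = c(100L, 150L),
                                offset_ms = c(200L, 250L))
  expect_error(segment_fixations(s, overlapping, none), "overlapping")
})

test_that("detected events partition the trial", {
  cfg <- sim_config(trial_ms = 4000, blink_rate_per_s = 0.3)
  tr <- simulate_trial(cfg, "control", seed = 5)
  ev <- detect_events(tr$samples)
  expect_equal(sum(ev$duration_ms), 4000L)
  ev2 <- ev[order(ev$onset_ms), ]
  expect_true(all(ev2$onset_ms[-1] == ev2$offset_ms[-nrow(ev2)]))
})
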