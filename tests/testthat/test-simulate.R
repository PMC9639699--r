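test_that("identical seeds give identical trials; schedules ignore rendering", {
  cfg <- sim_config(trial_ms = 3000)
  a <- simulate_trial(cfg, "control", seed = 11)
  b <- simulate_trial(cfg, "control", seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))

  # events-only mode draws the same schedule
  c <- simulate_trial(cfg, "control", seed = 11, render_samples = FALSE)
  expect_null(c$samples)
  expect_identical(as.data.frame(c$truth), as.data.frame(a$truth))
})

test_that("ground truth partitions the trial even with blinks carved out", {
  cfg <- sim_config(trial_ms = 5000, blink_rate_per_s = 0.6)
  tr <- simulate_trial(cfg, "peripheral", seed = 3, render_samples = FALSE)
  ev <- tr$truth[order(tr$truth$onset_ms), ]
  expect_equal(sum(ev$duration_ms), 5000L)
  expect_true(all(ev$onset_ms[-1] == ev$offset_ms[-nrow(ev)]))
})

test_that("the dataset emulates the full design with a valid manifest", {
  cfg <- sim_config(n_participants = 2, trials_per_condition = 30,
                    trial_ms = 1000, seed = 5)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d$manifest), 2 * 90)
  expect_silent(ambientfocal:::validate_manifest_design(d$manifest))
  # default design arithmetic: 42 participants x 90 trials
  dflt <- sim_config()
  expect_equal(dflt$n_participants * 3 * dflt$trials_per_condition, 3780)
  # truth covers every manifest trial
  expect_equal(nrow(dplyr::distinct(d$truth, participant_id, trial_index)),
               180)
})

test_that("noise-free simulation round-trips through the detector", {
  cfg <- sim_config(noise_sd_deg = 0, blink_rate_per_s = 0, trial_ms = 8000)
  tr <- simulate_trial(cfg, "control", seed = 17)
  det <- detect_events(tr$samples)
  cmp <- truth_compare(det, tr$truth, tol_ms = 2)
  expect_gte(cmp$hit_rate, 0.9)
  expect_equal(cmp$spurious, cmp$misses)  # boundary jitter, no inventions
  loose <- truth_compare(det, tr$truth, tol_ms = 5)
  expect_gte(loose$hit_rate, 0.99)
  expect_lte(loose$amplitude_error_q[["100%"]], 0.05)
})

test_that("mask-consistent targeting orders amplitudes across conditions", {
  cfg <- sim_config(n_participants = 2, trials_per_condition = 8, seed = 19)
  d <- simulate_dataset(cfg)
  ev <- dplyr::left_join(
    d$truth[d$truth$event_kind == "saccade", ],
    dplyr::distinct(d$manifest, participant_id, trial_index, condition),
    by = c("participant_id", "trial_index"))
  amp <- split(ev$amplitude_deg, ev$condition)
  expect_lt(mean(amp$central), mean(amp$control))
  expect_lt(mean(amp$control), mean(amp$peripheral))
  # window condition: amplitudes essentially within the 5-degree mask
  expect_gte(mean(amp$central <= 5 + 1e-9), 0.95)
  # peripheral distribution stochastically dominates the central one
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(quantile(amp$peripheral, qs) > quantile(amp$central, qs)))
})

test_that("realized fixation durations track the generator curve", {
  cfg <- sim_config(n_participants = 6, trials_per_condition = 10,
                    blink_rate_per_s = 0, seed = 23)
  d <- simulate_dataset(cfg)
  ev <- dplyr::left_join(
    d$truth,
    dplyr::distinct(d$manifest, participant_id, trial_index, condition),
    by = c("participant_id", "trial_index"))
  ev <- ev[!(ev$event_kind == "fixation" & ev$offset_ms >= cfg$trial_ms), ]
  tc <- bin_events(ev[ev$condition == "control", ], "fixation_duration_ms",
                   t_label = "midpoint")
  tc <- tc[tc$bin_index >= 2 & tc$bin_index <= 38, ]
  cp <- cfg$conditions$control
  curve <- cp$b_fd * exp(cp$a_fd / pmax(tc$t_s, cfg$clock_floor_s))
  # every bin mean within its own confidence envelope of the curve
  expect_true(all(abs(tc$mean - curve) < 2.5 * (tc$ci_hi - tc$mean)))
})

test_that("truth comparison counts hits, misses and spurious events", {
  truth <- dplyr::bind_rows(
    event_table("p01", 1, "fixation", 0, 300),
    event_table("p01", 1, "saccade", 300, 330, amplitude_deg = 4),
    event_table("p01", 1, "fixation", 330, 700)
  )
  self <- truth_compare(truth, truth)
  expect_equal(self$hits, 3L)
  expect_equal(self$misses + self$spurious, 0L)
  expect_equal(self$hit_rate, 1)
  expect_equal(unname(self$onset_error_q[["100%"]]), 0)

  # one planted micro-event the detector never saw: exactly one miss
  extra <- dplyr::bind_rows(truth,
                            event_table("p01", 1, "saccade", 150, 160,
                                        amplitude_deg = 0.05))
  cmp <- truth_compare(truth, extra)
  expect_equal(cmp$misses, 1L)
  expect_equal(cmp$spurious, 0L)

  other <- truth
  other$trial_index <- 2L
  expect_error(truth_compare(other, truth), "different trials")
})

test_that("raising the velocity threshold never finds more saccades", {
  cfg <- sim_config(trial_ms = 4000, noise_sd_deg = 0.02)
  tr <- simulate_trial(cfg, "control", seed = 29)
  n_default <- nrow(detect_saccades(tr$samples))
  n_strict <- nrow(detect_saccades(
    tr$samples, params = detection_params(min_velocity_deg_s = 60,
                                          min_accel_deg_s2 = 16000)))
  expect_lte(n_strict, n_default)
})
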