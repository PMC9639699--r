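abutting_events <- function() {
  dplyr::bind_rows(
    event_table("p01", 1, "fixation", 0, 250),        # first: unclassified
    event_table("p01", 1, "saccade", 250, 280, amplitude_deg = 6.2),
    event_table("p01", 1, "fixation", 280, 600),      # ambient
    event_table("p01", 1, "saccade", 600, 620, amplitude_deg = 3.0),
    event_table("p01", 1, "fixation", 620, 900),      # focal
    event_table("p01", 1, "saccade", 900, 930, amplitude_deg = 5.0),
    event_table("p01", 1, "fixation", 930, 1200),     # tie -> focal
    event_table("p01", 1, "blink", 1200, 1300),
    event_table("p01", 1, "fixation", 1300, 1600)     # after blink: unclassified
  )
}

test_that("fixations classify by preceding saccade amplitude with 5-deg tie to focal", {
  ev <- classify_fixations(abutting_events())
  fix <- ev[ev$event_kind == "fixation", ]
  expect_equal(fix$fixation_type,
               c("unclassified", "ambient", "focal", "focal", "unclassified"))
  expect_equal(fix$preceding_saccade_amplitude_deg,
               c(NA, 6.2, 3.0, 5.0, NA))
  expect_true(all(is.na(ev$fixation_type[ev$event_kind != "fixation"])))
  # classification partitions the fixations
  expect_equal(sum(table(fix$fixation_type)), nrow(fix))
})

test_that("interval slicing is half-open on onsets", {
  ev <- dplyr::bind_rows(
    event_table("p01", 1, "fixation", 1999, 2300),
    event_table("p01", 1, "fixation", 2000, 2300),
    event_table("p01", 1, "saccade", 6000, 6040),
    event_table("p01", 1, "fixation", 8000, 8400),
    event_table("p01", 1, "fixation", 5999, 6500)
  )
  out <- interval_slice(ev)
  expect_equal(out$interval,
               c("early", "neither", "late", "neither", "neither"))
})

test_that("aggregation takes participant means before grand means", {
  ev <- dplyr::bind_rows(
    event_table("p01", 1, "fixation", 0, 200),
    event_table("p01", 1, "fixation", 300, 600),
    event_table("p02", 1, "fixation", 0, 400)
  )
  ev$condition <- "control"
  tab <- aggregate_events(ev, "condition")
  expect_equal(tab$mean_fd_ms, c(250, 400))
  gm <- grand_means(tab)
  expect_equal(gm$mean_fd_ms, 325)   # not the event-weighted 300
})

test_that("empty cells appear with zero events and missing means", {
  ev <- dplyr::bind_rows(
    event_table("p01", 1, "fixation", 0, 200),
    event_table("p02", 2, "fixation", 0, 300)
  )
  ev$condition <- c("control", "central")
  tab <- aggregate_events(ev, "condition")
  expect_equal(nrow(tab), 4)   # 2 participants x 2 observed conditions
  empty <- tab[tab$participant_id == "p01" & tab$condition == "central", ]
  expect_equal(empty$n_events, 0L)
  expect_true(is.na(empty$mean_fd_ms))
})

test_that("grand means agree with an independent brute-force pass", {
  cfg <- sim_config(n_participants = 4, trials_per_condition = 3, seed = 21)
  d <- simulate_dataset(cfg)
  ev <- dplyr::left_join(
    d$truth,
    dplyr::distinct(d$manifest, participant_id, trial_index, condition),
    by = c("participant_id", "trial_index"))
  tab <- aggregate_events(ev, "condition")
  gm <- grand_means(tab)

  # brute force over raw events, no dplyr
  raw <- as.data.frame(ev[ev$event_kind == "fixation", ])
  for (cond in unique(raw$condition)) {
    pmeans <- c()
    for (p in unique(raw$participant_id)) {
      sel <- raw$condition == cond & raw$participant_id == p
      if (any(sel)) pmeans <- c(pmeans, mean(raw$duration_ms[sel]))
    }
    expect_equal(gm$mean_fd_ms[gm$condition == cond], mean(pmeans))
  }
})

test_that("the pipeline runs end to end deterministically and skips detection on events input", {
  cfg <- sim_config(n_participants = 2, trials_per_condition = 2, seed = 7)
  d <- simulate_dataset(cfg, render_samples = TRUE)

  r1 <- run_pipeline(samples = d$samples, manifest = d$manifest, max_bins = 40)
  d2 <- simulate_dataset(cfg, render_samples = TRUE)
  r2 <- run_pipeline(samples = d2$samples, manifest = d2$manifest,
                     max_bins = 40)
  expect_equal(as.data.frame(r1$events), as.data.frame(r2$events))
  expect_equal(r1$fits, r2$fits)

  # events input bypasses detection entirely
  r3 <- run_pipeline(events = d$truth, manifest = d$manifest)
  expect_s3_class(r3, "af_pipeline")
  expect_true(all(c("pooled", "central", "peripheral", "control") %in%
                    r3$fits$group))
  expect_error(run_pipeline(events = d$truth), "manifest")
})

test_that("fitted per-condition asymptote ordering matches the generator", {
  cfg <- sim_config(n_participants = 6, trials_per_condition = 10, seed = 33)
  d <- simulate_dataset(cfg)
  r <- run_pipeline(events = d$truth, manifest = d$manifest,
                    t_label = "midpoint")
  fd <- r$fits[r$fits$measure == "fixation_duration_ms" &
                 r$fits$group != "pooled", ]
  est <- fd$b[match(c("central", "peripheral", "control"), fd$group)]
  truth <- vapply(c("central", "peripheral", "control"),
                  function(cc) cfg$conditions[[cc]]$b_fd, numeric(1))
  expect_equal(order(est), order(truth))
})

test_that("pipeline outputs are written when a directory is given", {
  cfg <- sim_config(n_participants = 2, trials_per_condition = 2, seed = 9)
  d <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  run_pipeline(events = d$truth, manifest = d$manifest, output_dir = out)
  expect_true(all(file.exists(file.path(out, c(
    "clean_events.csv", "cleaning_report.csv", "timecourse_fd.csv",
    "timecourse_sa.csv", "fits.csv", "summary_condition.csv")))))
  back <- read_event_table(file.path(out, "clean_events.csv"))
  expect_gt(nrow(back), 0)
})
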