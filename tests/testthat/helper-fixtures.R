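# Event fixture with exactly 10 planted cleaning violations:
# 2 pre-onset events, 3 blink-adjacent events, 3 out-of-bounds fixation
# durations, and 2 trials with >= 4 s of total blink time.
make_cleaning_fixture <- function() {
  dplyr::bind_rows(
    # trial 1: pre-onset violations + blink-adjacent violations
    event_table("p01", 1, "fixation", -120, -20),     # pre-onset
    event_table("p01", 1, "saccade", -50, -10),       # pre-onset
    event_table("p01", 1, "blink", 5000, 5150),
    event_table("p01", 1, "fixation", 5200, 5500),    # gap 50 after blink
    event_table("p01", 1, "saccade", 4920, 4960),     # gap 40 before blink
    event_table("p01", 1, "fixation", 5100, 5400),    # overlaps blink
    event_table("p01", 1, "fixation", 0, 300),        # clean
    event_table("p01", 1, "saccade", 300, 330),       # clean
    event_table("p01", 1, "fixation", 330, 630),      # clean
    # trial 2: duration violations, no blinks
    event_table("p01", 2, "fixation", 0, 79),         # too short
    event_table("p01", 2, "fixation", 100, 1101),     # too long
    event_table("p01", 2, "fixation", 1200, 1250),    # too short
    event_table("p01", 2, "fixation", 1300, 1600),    # clean
    event_table("p01", 2, "saccade", 1600, 1640),     # clean
    event_table("p01", 2, "fixation", 1640, 1720),    # clean (exactly 80)
    event_table("p01", 2, "fixation", 1800, 2800),    # clean (exactly 1000)
    # trials 3 and 4: excessive total blink time
    event_table("p01", 3, "blink", 10000, 14000),     # 4000 ms, inclusive bound
    event_table("p01", 3, "fixation", 0, 300),
    event_table("p01", 3, "saccade", 300, 340),
    event_table("p02", 4, "blink", 1000, 3500),
    event_table("p02", 4, "blink", 8000, 9800),       # total 4300 ms
    event_table("p02", 4, "fixation", 4000, 4400)
  )
}

# Small manifest covering the full design for n participants.
make_manifest <- function(n_participants = 1, trials_per_condition = 30) {
  tpc <- trials_per_condition
  d <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_participants)),
                   slot = seq_len(3 * tpc), stringsAsFactors = FALSE)
  d <- d[order(d$participant_id, d$slot), ]
  tibble::tibble(
    participant_id = d$participant_id,
    trial_index = as.integer(d$slot),
    condition = rep(rep(c("central", "peripheral", "control"), each = tpc),
                    n_participants),
    scene_type = rep(rep(c("natural", "urban"), length.out = tpc),
                     3 * n_participants),
    scene_id = sprintf("scene_%03d", d$slot)
  )
}

manifest_csv_text <- function(manifest) {
  paste(c("participant_id,trial_index,condition,scene_type,scene_id",
          paste(manifest$participant_id, manifest$trial_index,
                manifest$condition, manifest$scene_type,
                manifest$scene_id, sep = ",")),
        collapse = "\n")
}

# Noiseless time course generated exactly from the asymptote model.
model_timecourse <- function(b, a, n_bins = 12, t_label = "end") {
  k <- seq_len(n_bins)
  t_s <- if (t_label == "end") k * 0.5 else (k - 0.5) * 0.5
  tibble::tibble(bin_index = k, t_s = t_s, mean = b * exp(a / t_s),
                 ci_lo = NA_real_, ci_hi = NA_real_,
                 n_participants = 10L, flagged = FALSE)
}
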