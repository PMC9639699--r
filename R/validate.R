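#' Parameter-recovery experiment on synthetic scanpaths
#'
#' Simulates full datasets from known generator parameters and re-fits
#' the asymptote model through the package's binning and fitting path,
#' once per seed. The estimator is matched to the generator: events
#' within 100 ms of a blink are removed (undoing the generator's blink
#' carving), right-censored final fixations (cut by the trial end) are
#' dropped, bins are labelled at their midpoints (the generator's mean
#' curve is clocked by fixation start time, which bin midpoints
#' approximate), and the last two bins — biased by end-of-trial
#' censoring — are excluded. Saccade fits additionally skip the first
#' two bins, as in the standard analysis.
#'
#' Truth values are the generator's `b_fd`/`a_fd` and, for amplitude,
#' the realized-mean asymptote [sim_amplitude_asymptote()] (the
#' generator draws amplitudes with log-normal *median* on the curve,
#' truncated by the condition's mask, so the binned means converge to
#' the truncated-log-normal mean rather than to `b_sa` itself).
#'
#' @param cfg A [sim_config()]; its `seed` field is replaced per run.
#' @param seeds Integer vector of dataset seeds.
#' @param max_bin Last bin included in the fits.
#' @return A tibble with one row per seed x condition: fitted
#'   `b_fd_hat`, `a_fd_hat`, `b_sa_hat` and the matching `*_true`
#'   columns.
#' @export
recover_generator_parameters <- function(cfg = sim_config(), seeds = 1:20,
                                         max_bin = 38) {
  rows <- purrr::map(seeds, function(sd) {
    cfg$seed <- as.integer(sd)
    d <- simulate_dataset(cfg)
    blinks <- d$truth[d$truth$event_kind == "blink", ]
    work <- d$truth[d$truth$event_kind != "blink", ]
    work <- drop_blink_adjacent(work, blinks, 100)$kept
    censored <- work$event_kind == "fixation" & work$offset_ms >= cfg$trial_ms
    work <- work[!censored, ]
    ev <- dplyr::left_join(
      work,
      dplyr::distinct(d$manifest, .data$participant_id, .data$trial_index,
                      .data$condition),
      by = c("participant_id", "trial_index"))
    purrr::map(CONDITIONS, function(cond) {
      sub <- ev[ev$condition == cond, ]
      tc_fd <- bin_events(sub, "fixation_duration_ms", t_label = "midpoint")
      f_fd <- fit_asymptote(tc_fd[tc_fd$bin_index <= max_bin, ])
      tc_sa <- bin_events(sub, "saccade_amplitude_deg", t_label = "midpoint")
      f_sa <- fit_asymptote(tc_sa[tc_sa$bin_index <= max_bin, ],
                            skip_bins = 2)
      cp <- cfg$conditions[[cond]]
      tibble::tibble(
        seed = sd, condition = cond,
        b_fd_hat = f_fd$b, a_fd_hat = f_fd$a, b_sa_hat = f_sa$b,
        b_fd_true = cp$b_fd, a_fd_true = cp$a_fd,
        b_sa_true = sim_amplitude_asymptote(cfg, cond),
        converged = f_fd$converged && f_sa$converged
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Early/late signature experiment on synthetic scanpaths
#'
#' For each seed, simulates a dataset and checks the qualitative
#' time-course signature the generator should reproduce: mean fixation
#' duration higher in the late (6-8 s) than the early (0-2 s) interval
#' in every condition, and mean saccade amplitude ordered
#' peripheral > control > central. Means are participant means first,
#' then unweighted grand means.
#'
#' @param cfg A [sim_config()]; its `seed` field is replaced per run.
#' @param seeds Integer vector of dataset seeds.
#' @return A tibble with one row per seed: logicals `fd_late_gt_early`
#'   and `sa_ordered`, plus the per-condition early/late fixation means
#'   and per-condition amplitude means.
#' @export
signature_experiment <- function(cfg = sim_config(), seeds = 1:20) {
  rows <- purrr::map(seeds, function(sd) {
    cfg$seed <- as.integer(sd)
    d <- simulate_dataset(cfg)
    ev <- dplyr::left_join(
      d$truth,
      dplyr::distinct(d$manifest, .data$participant_id, .data$trial_index,
                      .data$condition),
      by = c("participant_id", "trial_index")) |>
      interval_slice()
    el <- grand_means(aggregate_events(ev, c("condition", "interval")))
    sa <- grand_means(aggregate_events(ev, "condition"))
    fd <- function(cond, intv) {
      el$mean_fd_ms[el$condition == cond & el$interval == intv]
    }
    amp <- function(cond) sa$mean_sa_deg[sa$condition == cond]
    tibble::tibble(
      seed = sd,
      fd_late_gt_early = all(vapply(
        CONDITIONS, function(cc) fd(cc, "late") > fd(cc, "early"),
        logical(1))),
      sa_ordered = amp("peripheral") > amp("control") &&
        amp("control") > amp("central"),
      fd_early_central = fd("central", "early"),
      fd_late_central = fd("central", "late"),
      fd_early_peripheral = fd("peripheral", "early"),
      fd_late_peripheral = fd("peripheral", "late"),
      fd_early_control = fd("control", "early"),
      fd_late_control = fd("control", "late"),
      sa_central = amp("central"), sa_control = amp("control"),
      sa_peripheral = amp("peripheral")
    )
  })
  dplyr::bind_rows(rows)
}
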