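#' Bin event measures into 500-ms viewing-time intervals
#'
#' Assigns each event to a bin by its onset (`onset_ms` in
#' `[(k-1)*bin_ms, k*bin_ms)` puts it in bin `k`), computes
#' per-participant bin means first, then the across-participant grand
#' mean with a t-distribution confidence interval. Bins contributed to by
#' fewer than two participants are flagged and carry `NA` intervals.
#'
#' The bin's time label `t_s` defaults to the bin end (`k * bin_ms` in
#' seconds), the convention under which bin three is labelled 1.5 s;
#' `t_label = "midpoint"` labels bins at their centre instead.
#'
#' @param events Cleaned event table; grouping columns named in `by`
#'   (e.g. `condition`) must already be joined on.
#' @param measure `"fixation_duration_ms"` (fixation rows) or
#'   `"saccade_amplitude_deg"` (saccade rows).
#' @param bin_ms Bin width, ms.
#' @param by Optional character vector of grouping columns; one time
#'   course is computed per group.
#' @param t_label `"end"` or `"midpoint"` bin time labelling.
#' @param conf_level Confidence level for the across-participant interval.
#' @return A tibble of class `timecourse` with `by` columns plus
#'   `bin_index`, `t_s`, `mean`, `ci_lo`, `ci_hi`, `n_participants`,
#'   `flagged`.
#' @export
bin_events <- function(events,
                       measure = c("fixation_duration_ms",
                                   "saccade_amplitude_deg"),
                       bin_ms = 500, by = NULL,
                       t_label = c("end", "midpoint"),
                       conf_level = 0.95) {
  measure <- match.arg(measure)
  t_label <- match.arg(t_label)
  kind <- if (measure == "fixation_duration_ms") "fixation" else "saccade"
  ev <- events[events$event_kind == kind, ]
  if (nrow(ev) == 0) stop("no ", kind, " events to bin", call. = FALSE)
  ev$value <- if (kind == "fixation") as.numeric(ev$duration_ms) else
    ev$amplitude_deg
  ev$bin_index <- floor(ev$onset_ms / bin_ms) + 1L

  grp <- c(by, "bin_index")
  per_part <- ev |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "participant_id")))) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  alpha <- 1 - conf_level
  tc <- per_part |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean = mean(.data$m),
      n_participants = dplyr::n(),
      sem = stats::sd(.data$m) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flagged = .data$n_participants < 2,
      half = ifelse(.data$flagged, NA_real_,
                    stats::qt(1 - alpha / 2,
                              pmax(.data$n_participants - 1, 1)) *
                      .data$sem),
      ci_lo = .data$mean - .data$half,
      ci_hi = .data$mean + .data$half,
      t_s = if (t_label == "end") .data$bin_index * bin_ms / 1000 else
        (.data$bin_index - 0.5) * bin_ms / 1000
    ) |>
    dplyr::select(dplyr::all_of(by), "bin_index", "t_s", "mean",
                  "ci_lo", "ci_hi", "n_participants", "flagged") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
  attr(tc, "measure") <- measure
  attr(tc, "bin_ms") <- bin_ms
  attr(tc, "t_label") <- t_label
  class(tc) <- c("timecourse", class(tc))
  tc
}

#' Fit the nonlinear asymptote model to a binned time course
#'
#' Fits `mean ~ b * exp(a / t_s)` by unweighted nonlinear least squares
#' over the bin means. `b` is the asymptote (the value approached as
#' viewing time grows); `a` is the signed acceleration rate (negative
#' `a` gives a curve rising towards `b`, positive `a` a falling one).
#' Starting values are `b0` = mean of the last three bins and `a0` from
#' an ordinary regression of `log(mean)` on `1/t_s`; convergence
#' tolerance is 1e-10 on the parameters. The confidence interval for `b`
#' is t-based from the estimator covariance.
#'
#' For saccade amplitudes the first two bins are conventionally excluded
#' (`skip_bins = 2`) because amplitudes first rise to a peak around 1.5 s
#' before declining, which the single-exponential model cannot represent.
#'
#' @param tc A `timecourse` tibble for a single group (one row per bin).
#' @param skip_bins Drop bins with `bin_index <= skip_bins` before
#'   fitting.
#' @param conf_level Confidence level for `b_ci`.
#' @return An object of class `asymptote_fit`: list with `b`, `a`,
#'   `b_ci`, `b_se`, `a_se`, `skip_bins`, `residual_sse`, `df`,
#'   `converged`, `n_bins`.
#' @export
fit_asymptote <- function(tc, skip_bins = 0, conf_level = 0.95) {
  use <- tc[tc$bin_index > skip_bins & is.finite(tc$mean), ]
  use <- use[order(use$t_s), ]
  if (nrow(use) < 4) {
    stop("need at least 4 usable bins after skipping", call. = FALSE)
  }
  if (any(use$mean <= 0)) {
    stop("bin means must be positive for the exponential model",
         call. = FALSE)
  }
  b0 <- mean(utils::tail(use$mean, 3))
  ols <- stats::lm(log(mean) ~ I(1 / t_s), data = use)
  a0 <- unname(stats::coef(ols)[2])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      mean ~ b * exp(a / t_s), data = use,
      start = list(b = b0, a = a0),
      control = minpack.lm::nls.lm.control(
        ptol = 1e-10, ftol = 1e-10, maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(b = b0, a = a0, b_ci = c(NA_real_, NA_real_), b_se = NA_real_,
           a_se = NA_real_, skip_bins = skip_bins,
           residual_sse = NA_real_, df = NA_integer_,
           converged = FALSE, n_bins = nrow(use)),
      class = "asymptote_fit"
    ))
  }
  co <- stats::coef(fit)
  vc <- stats::vcov(fit)
  df <- nrow(use) - 2L
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(b = unname(co["b"]), a = unname(co["a"]),
         b_ci = unname(co["b"] + c(-1, 1) * tcrit * sqrt(vc["b", "b"])),
         b_se = sqrt(vc["b", "b"]), a_se = sqrt(vc["a", "a"]),
         skip_bins = skip_bins,
         residual_sse = sum(stats::resid(fit)^2), df = df,
         converged = TRUE, n_bins = nrow(use)),
    class = "asymptote_fit"
  )
}

#' @export
print.asymptote_fit <- function(x, ...) {
  cat(sprintf(
    "<asymptote_fit> b = %.4g [%.4g, %.4g], a = %.4g (%s, %d bins%s)\n",
    x$b, x$b_ci[1], x$b_ci[2], x$a,
    if (x$converged) "converged" else "NOT converged", x$n_bins,
    if (x$skip_bins > 0) sprintf(", first %d skipped", x$skip_bins) else ""))
  invisible(x)
}

#' Predicted value of the asymptote model
#'
#' Evaluates `b * exp(a / t_s)`.
#'
#' @param object An `asymptote_fit`.
#' @param t_s Viewing times in seconds, all strictly positive.
#' @param ... Unused.
#' @return Numeric vector of model predictions.
#' @export
predict.asymptote_fit <- function(object, t_s, ...) {
  if (any(!is.finite(t_s) | t_s <= 0)) {
    stop("t_s must be strictly positive", call. = FALSE)
  }
  object$b * exp(object$a / t_s)
}

#' Time at which a time course reaches its asymptote
#'
#' Returns the time label of the first bin (after the fit's skipped
#' bins) whose confidence interval contains the fitted asymptote `b`.
#'
#' @param fit A converged `asymptote_fit`.
#' @param tc The `timecourse` the fit was computed from.
#' @return The bin's `t_s` in seconds, or `NA_real_` if no bin's interval
#'   contains the asymptote.
#' @export
reach_time <- function(fit, tc) {
  if (!isTRUE(fit$converged)) {
    stop("reach_time requires a converged fit", call. = FALSE)
  }
  cand <- tc[tc$bin_index > fit$skip_bins, ]
  cand <- cand[order(cand$t_s), ]
  hit <- !is.na(cand$ci_lo) & cand$ci_lo <= fit$b & fit$b <= cand$ci_hi
  if (!any(hit)) return(NA_real_)
  cand$t_s[which(hit)[1]]
}
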