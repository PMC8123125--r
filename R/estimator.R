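#' Streaming estimator configuration
#'
#' Bundles the operating point of the whole pipeline. The defaults are the
#' chosen operating point of the method: filter constant `alpha = 0.22`
#' (period `p = 8`), a 15-sample fit buffer, LM damping starting at 0.1 with
#' adjustment factor 10.
#'
#' @param window_size Fit buffer length in samples (seconds at 1 Hz), `>= 3`
#'   (default 15).
#' @param alpha EMA filter constant in `(0, 1]` (default 0.22).
#' @param onset An [onset_config()].
#' @param lm An [lm_config()].
#' @param endpoint_mode `"asymptote"` reports the model asymptote `C`
#'   (available in true real time, the default); `"at_end_time"` evaluates the
#'   model at the real end of the analysis, which requires knowing it.
#' @param drop_guard_k When the onset config leaves `min_drop` at 0, the
#'   estimator derives one from the data: `drop_guard_k` times the MAD of the
#'   raw first differences over the first `baseline_n` samples (default 6).
#'   This keeps baseline noise wiggles from being confirmed as onsets while
#'   scaling automatically with the trace's own noise; a noiseless baseline
#'   yields 0, i.e. the guard disappears. Set to 0 to disable.
#' @param baseline_n Samples used for the noise estimate (default 10).
#' @return A list of class `"estimator_config"`.
#' @export
estimator_config <- function(window_size = 15L, alpha = 0.22,
                             onset = onset_config(), lm = lm_config(),
                             endpoint_mode = c("asymptote", "at_end_time"),
                             drop_guard_k = 6, baseline_n = 10L) {
  endpoint_mode <- match.arg(endpoint_mode)
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 3L) {
    stop("`window_size` must be >= 3 samples", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(drop_guard_k) || drop_guard_k < 0) {
    stop("`drop_guard_k` must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(onset, "onset_config"), inherits(lm, "lm_config"))
  structure(list(window_size = window_size, alpha = alpha, onset = onset,
                 lm = lm, endpoint_mode = endpoint_mode,
                 drop_guard_k = drop_guard_k,
                 baseline_n = as.integer(baseline_n)),
            class = "estimator_config")
}

#' Predict the final current from a fitted decay
#'
#' @param fit A converged [lm_fit()] result.
#' @param mode `"asymptote"` returns `C`, the limit of the decay model —
#'   the stabilized current I-infinity; `"at_end_time"` returns the model
#'   evaluated at the actual end of the analysis.
#' @param t_end End-of-analysis time in seconds (trace clock); required for
#'   `"at_end_time"`.
#' @param onset_time Onset time in seconds (trace clock), used to convert
#'   `t_end` to model time; default 0.
#' @return Predicted final current.
#' @export
predict_endpoint <- function(fit, mode = c("asymptote", "at_end_time"),
                             t_end = NULL, onset_time = 0) {
  stopifnot(inherits(fit, "decay_fit"))
  mode <- match.arg(mode)
  if (!fit$converged) stop("cannot predict from a non-converged fit", call. = FALSE)
  if (mode == "asymptote") {
    return(fit$params[["C"]])
  }
  if (is.null(t_end)) stop("`t_end` is required for mode = \"at_end_time\"", call. = FALSE)
  model_current(t_end - onset_time, fit$params)
}

#' Time saved by predicting early
#'
#' The analysis can stop once the fit buffer is full, i.e. at
#' `onset_time + window_size * dt`; everything the device would have recorded
#' after that is saved.
#'
#' @param trace_duration Full analysis duration, seconds.
#' @param onset_time Detected onset, seconds.
#' @param window_size Buffer length in samples.
#' @param dt Sampling interval, seconds (default 1).
#' @return `trace_duration - (onset_time + window_size * dt)`, floored at 0.
#' @examples
#' saved_time(60, 10, 15)  # 35 s
#' @export
saved_time <- function(trace_duration, onset_time, window_size, dt = 1) {
  pmax(0, trace_duration - (onset_time + window_size * dt))
}

stream_outcome <- function(status, reason = NA_character_, onset = NULL,
                           fit = NULL, I_estimated = NA_real_,
                           I_real = NA_real_, pe = NA_real_,
                           saved_time = NA_real_, onset_time = NA_real_,
                           trace_duration = NA_real_, window_size = NA_integer_) {
  structure(list(status = status, reason = reason, onset = onset, fit = fit,
                 I_estimated = I_estimated, I_real = I_real, pe = pe,
                 saved_time = saved_time, onset_time = onset_time,
                 trace_duration = trace_duration, window_size = window_size),
            class = "stream_outcome")
}

#' @export
print.stream_outcome <- function(x, ...) {
  if (x$status == "predicted") {
    cat(sprintf(
      "<predicted> I_est = %.4g (real %.4g, PE %.2f%%), onset %g s, saved %g s\n",
      x$I_estimated, x$I_real, x$pe, x$onset_time, x$saved_time))
  } else {
    cat(sprintf("<no algorithm> reason: %s\n", x$reason))
  }
  invisible(x)
}

#' Run the full real-time pipeline on one trace
#'
#' Processes the trace in arrival order: EMA filtering, causal onset
#' detection, accumulation of a `window_size`-sample buffer from the onset,
#' the Levenberg-Marquardt fit, and the endpoint prediction — everything the
#' device could have done while the measurement was still running. The fit
#' buffer is filled from the raw (cleaned) currents; the filtered signal only
#' drives onset detection, since the filter's lag distorts the decay kinetics.
#'
#' A trace where no prediction can be emitted is classified "no algorithm":
#' * `trace_rejected` — the input failed [clean_trace()];
#' * `buffer_not_filled` — the analysis ended (the signal stabilized) before
#'   `window_size` samples were available;
#' * `onset_too_late` — no onset was committed before the trace ran out, or
#'   the onset landed so near the end that the buffer could not fill;
#' * `fit_failed` — the LM fit did not converge (including a fitted growth,
#'   `B < 0`).
#'
#' @param trace An [amperogram()] or a [clean_trace()] rejection.
#' @param config An [estimator_config()].
#' @return A `"stream_outcome"`: `status` (`"predicted"` or
#'   `"no_algorithm"`), `reason`, the onset and fit objects, `I_estimated`,
#'   `I_real` (last trace sample), `pe` (absolute percentage error vs
#'   `I_real`), `saved_time` and bookkeeping fields.
#' @examples
#' tr <- generate_trace(trace_spec(seed = 7))$trace
#' run_streaming(tr, estimator_config())
#' @export
run_streaming <- function(trace, config = estimator_config()) {
  stopifnot(inherits(config, "estimator_config"))
  if (is_rejected(trace)) {
    return(stream_outcome("no_algorithm", reason = "trace_rejected"))
  }
  stopifnot(inherits(trace, "amperogram"))
  n <- length(trace$currents)
  w <- config$window_size
  duration <- trace_duration(trace)

  if (n < w) {
    return(stream_outcome("no_algorithm", reason = "buffer_not_filled",
                          trace_duration = duration, window_size = w))
  }

  filtered <- ema_filter(trace, config$alpha)

  ocfg <- config$onset
  if (ocfg$min_drop == 0 && config$drop_guard_k > 0) {
    # derive a noise-scaled drop guard from the earliest (pre-onset) samples
    base <- trace$currents[seq_len(min(config$baseline_n, n))]
    guard <- config$drop_guard_k * stats::mad(diff(base))
    if (is.finite(guard) && guard > 0) {
      ocfg <- onset_config(ocfg$confirm_k, ocfg$rise_eps, min_drop = guard)
    }
  }
  onset <- find_onset(filtered, ocfg)

  if (!onset$detected) {
    return(stream_outcome("no_algorithm", reason = "onset_too_late",
                          onset = onset, trace_duration = duration,
                          window_size = w))
  }
  if (onset$onset_index + w - 1L > n) {
    return(stream_outcome("no_algorithm", reason = "onset_too_late",
                          onset = onset, onset_time = onset$onset_time,
                          trace_duration = duration, window_size = w))
  }

  idx <- onset$onset_index:(onset$onset_index + w - 1L)
  window <- fit_window(trace$times[idx] - trace$times[onset$onset_index],
                       trace$currents[idx])
  fit <- tryCatch(lm_fit(window, config$lm), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(stream_outcome("no_algorithm", reason = "fit_failed", onset = onset,
                          fit = fit, onset_time = onset$onset_time,
                          trace_duration = duration, window_size = w))
  }

  I_est <- predict_endpoint(fit, mode = config$endpoint_mode,
                            t_end = trace$times[n], onset_time = onset$onset_time)
  I_real <- trace$currents[n]
  pe <- if (I_real != 0) percent_error(I_real, I_est) else NA_real_
  stream_outcome("predicted", onset = onset, fit = fit, I_estimated = I_est,
                 I_real = I_real, pe = pe,
                 saved_time = saved_time(duration, onset$onset_time, w, trace$dt),
                 onset_time = onset$onset_time, trace_duration = duration,
                 window_size = w)
}
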