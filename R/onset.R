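#' First derivative of a trace
#'
#' Backward first difference of the (usually filtered) current, the signal the
#' onset detector scans: once the enzymatic reaction starts, the current drops
#' exponentially, so the derivative minimum marks the start of the decay.
#'
#' @param trace An [amperogram()] of length >= 2.
#' @return Numeric vector of length `length(trace) - 1`, in current units per
#'   second; element `i` is `(y[i+1] - y[i]) / dt`.
#' @export
trace_derivative <- function(trace) {
  stopifnot(inherits(trace, "amperogram"))
  if (length(trace$currents) < 2L) {
    stop("need at least 2 samples for a derivative", call. = FALSE)
  }
  diff(trace$currents) / trace$dt
}

#' Onset detector configuration
#'
#' The injection of the sample perturbs the current for a stochastic
#' homogenization interval before the enzymatic decay begins; the detector
#' must skip those spikes and still commit causally (in real time). The knobs:
#'
#' * `confirm_k` — a derivative-minimum candidate is only declared the onset
#'   once this many subsequent derivative samples have failed to undercut it
#'   (causal confirmation horizon, samples).
#' * `rise_eps` — if the derivative exceeds `+rise_eps` while a candidate is
#'   pending, the signal is rising (a spike): the candidate is discarded and
#'   the search re-arms.
#' * `min_drop` — minimum cumulative drop of the signal from the trace start,
#'   evaluated at confirmation time, for an onset to be declared; guards
#'   against confirming baseline noise wiggles. `0` requires any positive drop.
#'
#' @param confirm_k Confirmation horizon in samples, `>= 1` (default 3).
#' @param rise_eps Re-arm threshold on the derivative, `>= 0` (default 0).
#' @param min_drop Minimum cumulative drop in current units, `>= 0` (default 0).
#' @return A list of class `"onset_config"`.
#' @export
onset_config <- function(confirm_k = 3L, rise_eps = 0, min_drop = 0) {
  confirm_k <- as.integer(confirm_k)
  if (is.na(confirm_k) || confirm_k < 1L) stop("`confirm_k` must be >= 1", call. = FALSE)
  if (!is.finite(rise_eps) || rise_eps < 0) stop("`rise_eps` must be >= 0", call. = FALSE)
  if (!is.finite(min_drop) || min_drop < 0) stop("`min_drop` must be >= 0", call. = FALSE)
  structure(list(confirm_k = confirm_k, rise_eps = rise_eps,
                 min_drop = min_drop), class = "onset_config")
}

#' Detect the onset of the enzymatic decay
#'
#' Scans the derivative of a filtered trace causally, maintaining the running
#' minimum. A candidate minimum at index `m` becomes the onset once
#' `confirm_k` subsequent derivative samples are all above it, provided the
#' signal has dropped by more than `min_drop` from the trace start by
#' confirmation time. If the derivative rises above `+rise_eps` while a
#' candidate is pending — an injection spike — or a confirmed candidate fails
#' the drop test, the candidate is discarded and the search re-arms
#' (`restarts` is incremented). Only strictly negative derivative samples can
#' be candidates: an onset is a decay, by definition.
#'
#' The decision at confirmation index `i` uses samples `1..i` only, so feeding
#' the trace incrementally gives the same answer as batch processing.
#'
#' @param filtered An [amperogram()], normally the output of [ema_filter()].
#' @param config An [onset_config()].
#' @return A list of class `"onset_result"`: `detected` (logical),
#'   `onset_index` (1-based sample index into the trace), `onset_time`
#'   (seconds), `derivative_at_onset` (current/s, negative when detected),
#'   `restarts` (count), and `decided_index` (the sample at which the decision
#'   was committed; `NA` when not detected).
#' @examples
#' tr <- amperogram(0:29, c(rep(12, 10), 10 * exp(-0.2 * (0:19)) + 2))
#' find_onset(tr)
#' @export
find_onset <- function(filtered, config = onset_config()) {
  stopifnot(inherits(filtered, "amperogram"), inherits(config, "onset_config"))
  y <- filtered$currents
  n <- length(y)
  d <- diff(y) / filtered$dt  # d[j] is the derivative at trace index j + 1

  best_i <- NA_integer_   # trace index of the candidate minimum
  best_d <- Inf
  since_best <- 0L
  restarts <- 0L

  not_detected <- function() {
    structure(list(detected = FALSE, onset_index = NA_integer_,
                   onset_time = NA_real_, derivative_at_onset = NA_real_,
                   restarts = restarts, decided_index = NA_integer_),
              class = "onset_result")
  }
  if (n < 2L) return(not_detected())

  for (i in 2:n) {
    di <- d[i - 1L]
    if (!is.na(best_i) && di > config$rise_eps) {
      # signal rising under a pending candidate: spike, re-arm
      best_i <- NA_integer_; best_d <- Inf; since_best <- 0L
      restarts <- restarts + 1L
    }
    if (di < 0 && di < best_d) {
      best_i <- i; best_d <- di; since_best <- 0L
    } else if (!is.na(best_i)) {
      since_best <- since_best + 1L
      if (since_best >= config$confirm_k) {
        drop <- y[1] - y[i]
        if (drop > config$min_drop) {
          return(structure(
            list(detected = TRUE, onset_index = best_i,
                 onset_time = filtered$times[best_i],
                 derivative_at_onset = best_d, restarts = restarts,
                 decided_index = i),
            class = "onset_result"))
        }
        # confirmed but the signal has not really dropped: noise, re-arm
        best_i <- NA_integer_; best_d <- Inf; since_best <- 0L
        restarts <- restarts + 1L
      }
    }
  }
  not_detected()
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<onset> index %d (t = %g s), derivative %.4g /s, %d restart(s)\n",
      x$onset_index, x$onset_time, x$derivative_at_onset, x$restarts))
  } else {
    cat(sprintf("<onset> not detected (%d restart(s))\n", x$restarts))
  }
  invisible(x)
}
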