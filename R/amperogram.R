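#' Amperogram trace
#'
#' An amperogram is the current-vs-time record of an amperometric biosensor
#' measurement: the device holds the electrochemical cell at a fixed potential
#' and registers the current produced by the enzyme-mediated redox reaction,
#' typically once per second. `amperogram()` builds a validated trace object
#' from a time grid and a current series.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param currents Numeric vector of currents (device units, e.g. nA), same
#'   length as `times`.
#' @param dt Sampling interval in seconds. Defaults to the median spacing of
#'   `times`.
#' @param meta Optional named list of free-form provenance tags.
#'
#' @return An object of class `"amperogram"`: a list with elements `times`,
#'   `currents`, `dt` and `meta`.
#'
#' @details Validation enforces: at least two samples, equal lengths, finite
#'   values, and uniform spacing (`|diff(times) - dt| < 1e-9`). Dirty series
#'   should go through [clean_trace()] first.
#'
#' @examples
#' tr <- amperogram(0:9, 10 - 0.5 * (0:9))
#' tr
#' @export
amperogram <- function(times, currents, dt = NULL, meta = list()) {
  times <- as.numeric(times)
  currents <- as.numeric(currents)
  if (length(times) != length(currents)) {
    stop("`times` and `currents` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("an amperogram needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(currents))) {
    stop("`times` and `currents` must be finite; run clean_trace() first",
         call. = FALSE)
  }
  steps <- diff(times)
  if (any(steps <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (is.null(dt)) dt <- stats::median(steps)
  if (any(abs(steps - dt) >= 1e-9)) {
    stop("`times` must be uniformly spaced at dt = ", dt, call. = FALSE)
  }
  structure(
    list(times = times, currents = currents, dt = dt, meta = meta),
    class = "amperogram"
  )
}

#' @export
print.amperogram <- function(x, ...) {
  cat(sprintf(
    "<amperogram> %d samples, dt = %g s, t in [%g, %g] s, current in [%.4g, %.4g]\n",
    length(x$times), x$dt, x$times[1], x$times[length(x$times)],
    min(x$currents), max(x$currents)
  ))
  invisible(x)
}

#' @export
length.amperogram <- function(x) length(x$times)

#' @export
as.data.frame.amperogram <- function(x, ...) {
  data.frame(time_s = x$times, current = x$currents)
}

#' Total duration of a trace, in seconds
#'
#' @param trace An [amperogram()].
#' @return Last time minus first time, in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "amperogram"))
  trace$times[length(trace$times)] - trace$times[1]
}

#' Screen a raw current series for acquisition errors
#'
#' Device logs occasionally contain inconsistent records or a dropped signal;
#' such traces are removed before analysis rather than repaired. `clean_trace()`
#' either promotes a raw `(time, current)` series to a validated
#' [amperogram()] or returns a rejection value carrying the reason.
#'
#' @param times,currents Numeric vectors of the raw series.
#' @param dt Expected sampling interval in seconds (default 1).
#' @param min_len Minimum acceptable number of samples (default 2).
#' @param gap_max A run of at least this many consecutive samples at exactly
#'   zero is treated as loss of signal (default 3).
#' @param meta Passed to [amperogram()].
#'
#' @return Either an `"amperogram"` or an object of class `"trace_rejection"`,
#'   a list with a `reason` in `"non_finite_values"`, `"too_short"`,
#'   `"non_uniform_sampling"`, `"signal_loss"`. Rejection is a value, not an
#'   error condition; test with [is_rejected()].
#' @examples
#' clean_trace(0:4, c(5, 4, 0, 0, 0))   # rejected: signal loss run of 3
#' @export
clean_trace <- function(times, currents, dt = 1, min_len = 2L, gap_max = 3L,
                        meta = list()) {
  times <- suppressWarnings(as.numeric(times))
  currents <- suppressWarnings(as.numeric(currents))
  reject <- function(reason, detail = NULL) {
    structure(list(reason = reason, detail = detail), class = "trace_rejection")
  }
  if (anyNA(times) || anyNA(currents) ||
      !all(is.finite(times)) || !all(is.finite(currents))) {
    bad <- which(!is.finite(currents) | !is.finite(times))
    return(reject("non_finite_values", detail = bad))
  }
  if (length(times) < max(2L, min_len) || length(times) != length(currents)) {
    return(reject("too_short"))
  }
  steps <- diff(times)
  if (any(steps <= 0) || any(abs(steps - dt) >= 1e-9)) {
    return(reject("non_uniform_sampling", detail = which(abs(steps - dt) >= 1e-9)))
  }
  # loss of signal: the ADC reads back a flat exact zero for gap_max+ samples
  runs <- rle(currents == 0)
  if (any(runs$values & runs$lengths >= gap_max)) {
    return(reject("signal_loss"))
  }
  amperogram(times, currents, dt = dt, meta = meta)
}

#' @rdname clean_trace
#' @param x Result of [clean_trace()].
#' @export
is_rejected <- function(x) inherits(x, "trace_rejection")

#' @export
print.trace_rejection <- function(x, ...) {
  cat("<trace rejected>", x$reason, "\n")
  invisible(x)
}
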