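#' Specification of one synthetic amperogram
#'
#' Emulates the structure of a real amperometric measurement: a baseline
#' plateau at `I0 = A + C`, a stochastic injection/homogenization transient
#' carrying random spikes (and optionally an initial overshoot bump), the
#' one-phase exponential decay toward the asymptote `C`, additive Gaussian
#' white noise, and an automatic end of analysis once the filtered slope has
#' stabilized. The baseline equals `A + C` by construction so the signal is
#' continuous at the injection hand-off and `A` is exactly the span
#' (`I0 - I_inf`), the quantity proportional to the analyte concentration.
#'
#' @param A Span amplitude, current units (default 50).
#' @param B Decay rate, 1/s, `> 0` (default 0.12).
#' @param C Asymptotic current I-infinity (default 40).
#' @param plateau_s Pre-injection plateau duration, s (default 10).
#' @param transient_s Homogenization duration, s (default 5).
#' @param spike_prob Per-sample probability of an injection spike during the
#'   transient (default 0.3).
#' @param spike_amp Spike amplitude scale; each spike adds
#'   `spike_amp * U(0.5, 1.5)` (default 5).
#' @param overshoot_amp Amplitude of an optional decaying positive bump at the
#'   start of the transient (default 0, disabled).
#' @param noise_sigma SD of the additive Gaussian noise (default `0.01 * A`).
#' @param dt Sampling interval, s (default 1).
#' @param seed RNG seed for this trace (default 1).
#' @param stab_slope Stabilization threshold: the analysis ends once the
#'   magnitude of the filtered slope stays below this for `stab_len`
#'   consecutive samples after onset. Default `0.002 * A` (0.2% of span per
#'   second).
#' @param stab_len Consecutive quiet samples required (default 5).
#' @param stab_win Averaging window of the stabilization monitor, samples
#'   (default 12): the monitored slope is the signal drop over the trailing
#'   `stab_win` samples divided by its duration. The boxcar must average hard
#'   enough that the slope noise floor (`sqrt(2) * noise_sigma / stab_win`)
#'   sits below `stab_slope`, otherwise the end of the analysis is set by
#'   noise rather than by the reaction flattening out.
#' @param max_s Hard cap on the trace duration, s (default 300); a trace that
#'   never stabilizes is truncated there and flagged.
#' @return A list of class `"trace_spec"`.
#' @export
trace_spec <- function(A = 50, B = 0.12, C = 40, plateau_s = 10,
                       transient_s = 5, spike_prob = 0.3, spike_amp = 5,
                       overshoot_amp = 0, noise_sigma = 0.01 * A, dt = 1,
                       seed = 1L, stab_slope = 0.002 * A, stab_len = 5L,
                       stab_win = 12L, max_s = 300) {
  if (B <= 0) stop("`B` must be > 0 (a decay)", call. = FALSE)
  if (plateau_s < 0 || transient_s < 0) stop("durations must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (spike_prob < 0 || spike_prob > 1) stop("`spike_prob` must be in [0, 1]", call. = FALSE)
  structure(list(A = A, B = B, C = C, I0 = A + C, plateau_s = plateau_s,
                 transient_s = transient_s, spike_prob = spike_prob,
                 spike_amp = spike_amp, overshoot_amp = overshoot_amp,
                 noise_sigma = noise_sigma, dt = dt, seed = as.integer(seed),
                 stab_slope = stab_slope, stab_len = as.integer(stab_len),
                 stab_win = as.integer(stab_win), max_s = max_s),
            class = "trace_spec")
}

#' Generate one synthetic amperogram with ground truth
#'
#' Builds the piecewise signal described by a [trace_spec()], adds noise and
#' injection spikes, and ends the analysis with the same stabilization rule a
#' device controller would apply: the first time the trailing-window filtered
#' slope magnitude stays below `stab_slope` for `stab_len` consecutive
#' samples after the onset. Identical specs (including seed) produce
#' identical traces.
#'
#' @param spec A [trace_spec()].
#' @return A list with `trace` (an [amperogram()]) and `truth`: a list with
#'   the true `onset_time` (`plateau_s + transient_s`, snapped to the
#'   sampling grid), `I_inf` (`= C`),
#'   `span` (`= A`), `A`, `B`, `C`, `end_time`, and `truncated` (`TRUE` when
#'   the cap ended the trace before stabilization).
#' @examples
#' g <- generate_trace(trace_spec(A = 30, B = 0.15, C = 25, seed = 42))
#' g$trace
#' g$truth$I_inf
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  dt <- spec$dt
  n_max <- floor(spec$max_s / dt) + 1L
  times <- seq(0, by = dt, length.out = n_max)
  # snap the onset to the sampling grid so the ground truth is exact at a sample
  t_onset <- round((spec$plateau_s + spec$transient_s) / dt) * dt

  signal <- ifelse(times < t_onset, spec$I0,
                   spec$A * exp(-spec$B * (times - t_onset)) + spec$C)

  in_transient <- times >= spec$plateau_s & times < t_onset
  if (any(in_transient)) {
    k <- sum(in_transient)
    spikes <- stats::rbinom(k, 1L, spec$spike_prob) *
      spec$spike_amp * stats::runif(k, 0.5, 1.5)
    signal[in_transient] <- signal[in_transient] + spikes
    if (spec$overshoot_amp > 0) {
      tt <- times[in_transient] - spec$plateau_s
      signal[in_transient] <- signal[in_transient] +
        spec$overshoot_amp * exp(-3 * tt / max(spec$transient_s, dt))
    }
  }
  if (spec$noise_sigma > 0) {
    signal <- signal + stats::rnorm(n_max, 0, spec$noise_sigma)
  }

  # device-side end of analysis: the boxcar-filtered slope (signal drop over
  # the trailing stab_win samples) must stay quiet for stab_len samples
  k <- min(spec$stab_win, n_max - 1L)
  idx <- (k + 1L):n_max
  slope <- abs((signal[idx] - signal[idx - k]) / (k * dt))  # slope at sample idx
  onset_idx <- which(times >= t_onset)[1]
  quiet <- slope < spec$stab_slope
  end_idx <- n_max
  truncated <- TRUE
  first_check <- max(onset_idx + spec$stab_len, k + spec$stab_len)
  if (first_check <= n_max) {
    for (i in first_check:n_max) {
      # quiet[j] corresponds to sample j + k
      if (all(quiet[(i - k - spec$stab_len + 1L):(i - k)])) {
        end_idx <- i
        truncated <- FALSE
        break
      }
    }
  }

  trace <- amperogram(times[1:end_idx], signal[1:end_idx], dt = dt,
                      meta = list(seed = spec$seed, synthetic = TRUE))
  truth <- list(onset_time = t_onset, I_inf = spec$C, span = spec$A,
                A = spec$A, B = spec$B, C = spec$C,
                end_time = times[end_idx], truncated = truncated)
  list(trace = trace, truth = truth)
}

#' Default cohort sampling ranges
#'
#' Uniform ranges for the per-trace spec fields, chosen so that cohort
#' analysis durations center near one minute — the typical duration of a
#' sample analysis on an amperometric biosensor bench: spans of 20-80 current
#' units, decay rates 0.06-0.4 /s, asymptotes 20-60, 5-20 s plateaus, 2-8 s
#' homogenization transients, occasional injection spikes, and noise at 1% of
#' span (`noise_frac`).
#'
#' @return Named list of `c(lo, hi)` ranges (with `noise_frac` the noise SD
#'   as a fraction of span `A`).
#' @export
default_cohort_ranges <- function() {
  list(A = c(20, 80), B = c(0.06, 0.4), C = c(20, 60),
       plateau_s = c(5, 20), transient_s = c(2, 8),
       spike_prob = c(0.3, 0.3), spike_amp = c(2, 10),
       noise_frac = c(0.01, 0.01))
}

#' Generate a reproducible cohort of synthetic amperograms
#'
#' Draws `n` independent trace specs uniformly from `ranges` and generates
#' each with its own derived seed. The whole cohort is a pure function of
#' `(n, ranges, seed)`. Stands in for a bench dataset of repeated enzymatic
#' measurements.
#'
#' @param n Number of traces, `>= 1`.
#' @param ranges Per-field `c(lo, hi)` ranges as in [default_cohort_ranges()];
#'   fields not listed keep the [trace_spec()] defaults.
#' @param seed Cohort seed.
#' @return A list of `n` elements, each `list(trace, truth, spec)`.
#' @examples
#' cohort <- generate_cohort(3, seed = 11)
#' sapply(cohort, function(x) x$truth$I_inf)
#' @export
generate_cohort <- function(n, ranges = default_cohort_ranges(), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  base <- default_cohort_ranges()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop("invalid range for `", nm, "`: need finite c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
    base[[nm]] <- r
  }
  ranges <- base
  set.seed(seed)
  draws <- lapply(ranges, function(r) stats::runif(n, r[1], r[2]))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    sp <- trace_spec(
      A = draws$A[i], B = draws$B[i], C = draws$C[i],
      plateau_s = draws$plateau_s[i], transient_s = draws$transient_s[i],
      spike_prob = draws$spike_prob[i], spike_amp = draws$spike_amp[i],
      noise_sigma = draws$noise_frac[i] * draws$A[i],
      stab_slope = 0.002 * draws$A[i], seed = seeds[i])
    g <- generate_trace(sp)
    list(trace = g$trace, truth = g$truth, spec = sp)
  })
}
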