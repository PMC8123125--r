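test_that("a noiseless spec is exactly piecewise plateau + model decay", {
  sp <- trace_spec(A = 10, B = 0.2, C = 2, plateau_s = 10, transient_s = 0,
                   spike_prob = 0, noise_sigma = 0, seed = 2)
  g <- generate_trace(sp)
  tr <- g$trace
  pre <- tr$times < g$truth$onset_time
  expect_true(all(abs(tr$currents[pre] - 12) < 1e-12))
  post <- !pre
  expect_lt(max(abs(tr$currents[post] -
                    model_current(tr$times[post] - g$truth$onset_time,
                                  decay_params(10, 0.2, 2)))), 1e-12)
  # and the fitter inverts the generator exactly from the true onset
  idx <- which(post)[1:15]
  w <- fit_window(tr$times[idx] - g$truth$onset_time, tr$currents[idx])
  fit <- lm_fit(w)
  expect_equal(unname(unclass(fit$params)), c(10, 0.2, 2), tolerance = 1e-4)
})

test_that("generation is deterministic in the seed", {
  sp <- trace_spec(seed = 99)
  g1 <- generate_trace(sp)
  g2 <- generate_trace(sp)
  expect_identical(g1$trace$currents, g2$trace$currents)
  expect_identical(g1$truth, g2$truth)

  c1 <- generate_cohort(5, seed = 17)
  c2 <- generate_cohort(5, seed = 17)
  expect_identical(lapply(c1, function(x) x$trace$currents),
                   lapply(c2, function(x) x$trace$currents))
})

test_that("forced spikes rise above the baseline during the transient", {
  sp <- trace_spec(A = 20, B = 0.2, C = 10, plateau_s = 5, transient_s = 6,
                   spike_prob = 1, spike_amp = 5, noise_sigma = 0, seed = 12)
  g <- generate_trace(sp)
  tr <- g$trace
  transient <- tr$times >= 5 & tr$times < 11
  expect_true(any(tr$currents[transient] > 30))
})

test_that("ground truth is consistent: onset, span, asymptote", {
  cohort <- generate_cohort(20, seed = 6)
  for (el in cohort) {
    expect_equal(el$truth$onset_time,
                 round(el$spec$plateau_s + el$spec$transient_s))
    expect_equal(el$truth$I_inf, el$spec$C)
    # span conservation at the onset sample, within the noise
    i0 <- which(el$trace$times >= el$truth$onset_time)[1]
    expect_lt(abs((el$trace$currents[i0] - el$truth$I_inf) - el$truth$span),
              max(3 * el$spec$noise_sigma, 1e-9))
  }
})

test_that("the detector recovers the constructed onset on noiseless traces", {
  cfg <- onset_config()
  for (seed in 1:10) {
    sp <- trace_spec(A = 25, B = 0.12, C = 30, plateau_s = 8 + seed,
                     transient_s = 0, spike_prob = 0, noise_sigma = 0,
                     seed = seed)
    g <- generate_trace(sp)
    res <- find_onset(g$trace, cfg)
    expect_true(res$detected)
    expect_lte(abs(res$onset_time - g$truth$onset_time), cfg$confirm_k + 2)
  }
})

test_that("cohort durations track the closed-form decay horizon", {
  # with all spec fields pinned, the end time is onset + the time for the
  # boxcar slope to fall under stab_slope (plus the quiet run)
  ranges <- list(A = c(50, 50), B = c(0.2, 0.2), C = c(40, 40),
                 plateau_s = c(10, 10), transient_s = c(4, 4),
                 spike_prob = c(0, 0), noise_frac = c(0, 0))
  cohort <- generate_cohort(3, ranges = ranges, seed = 8)
  k <- 12
  tau <- k + log((1 - exp(-0.2 * k)) / (0.002 * k)) / 0.2  # slope = stab_slope
  for (el in cohort) {
    expect_lt(abs(el$truth$end_time - (14 + tau)), 8)
  }
})

test_that("invalid cohort ranges are refused", {
  expect_error(generate_cohort(3, ranges = list(A = c(5, 2))), "invalid range")
  expect_error(generate_cohort(0), ">= 1")
})
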