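fake_fit <- function(A, B, C, converged = TRUE) {
  structure(list(params = decay_params(A, B, C), sse = 0, n_iter = 1L,
                 converged = converged, lambda_final = 0.1, history = NULL),
            class = "decay_fit")
}

test_that("endpoint prediction returns the asymptote or the end-time value", {
  expect_equal(predict_endpoint(fake_fit(0, 1, 7)), 7)
  expect_equal(predict_endpoint(fake_fit(10, 0.2, 2)), 2)
  expect_equal(predict_endpoint(fake_fit(10, 0.2, 2), "at_end_time",
                                t_end = 40, onset_time = 10),
               2 + 10 * exp(-6), tolerance = 1e-12)
  expect_error(predict_endpoint(fake_fit(10, 0.2, 2), "at_end_time"), "t_end")
  expect_error(predict_endpoint(fake_fit(1, 1, 1, converged = FALSE)),
               "non-converged")
})

test_that("saved time is the remaining duration, floored at zero", {
  expect_equal(saved_time(60, 10, 15), 35)
  expect_equal(saved_time(25, 10, 15), 0)
  expect_equal(saved_time(62, 11, 15), 36)
  expect_equal(saved_time(100, 20, 15, dt = 2), 50)
})

test_that("a clean synthetic trace is predicted with small error", {
  g <- generate_trace(trace_spec(A = 10, B = 0.15, C = 20, plateau_s = 20,
                                 transient_s = 0, spike_prob = 0,
                                 noise_sigma = 0.05, seed = 5))
  out <- run_streaming(g$trace)
  expect_equal(out$status, "predicted")
  expect_lt(out$pe, 5)
  expect_equal(out$I_real, g$trace$currents[length(g$trace$currents)])
  expect_equal(out$saved_time,
               trace_duration(g$trace) - (out$onset_time + 15))
})

test_that("short traces and rejected traces get no prediction", {
  short <- amperogram(0:9, 10 * exp(-0.3 * (0:9)) + 1)
  out <- run_streaming(short, estimator_config(window_size = 15))
  expect_equal(out$status, "no_algorithm")
  expect_equal(out$reason, "buffer_not_filled")

  rej <- clean_trace(0:9, c(1:4, NA, 6:10))
  out2 <- run_streaming(rej)
  expect_equal(out2$reason, "trace_rejected")

  # onset so near the end that the buffer cannot fill
  y <- c(rep(10, 40), 10 - 2 * (1:5))
  late <- amperogram(0:44, y)
  out3 <- run_streaming(late, estimator_config(window_size = 15,
                                               drop_guard_k = 0))
  expect_equal(out3$status, "no_algorithm")
  expect_equal(out3$reason, "onset_too_late")
})

test_that("truncating a trace after the decision changes nothing (causality)", {
  cohort <- generate_cohort(10, seed = 3)
  cfg <- estimator_config()
  for (el in cohort) {
    out <- run_streaming(el$trace, cfg)
    if (out$status != "predicted") next
    tr <- el$trace
    # keep everything up to the moment the prediction was emitted
    keep <- max(out$onset$decided_index,
                out$onset$onset_index + cfg$window_size - 1L)
    prefix <- amperogram(tr$times[1:keep], tr$currents[1:keep], dt = tr$dt)
    out2 <- run_streaming(prefix, cfg)
    expect_equal(out2$status, "predicted")
    expect_equal(out2$I_estimated, out$I_estimated)
    expect_equal(out2$onset_time, out$onset_time)
  }
})

test_that("saved time shrinks as the window grows, trace by trace", {
  cohort <- generate_cohort(20, seed = 4)
  for (el in cohort[1:5]) {
    saved <- sapply(c(10, 15, 20, 25), function(w) {
      out <- run_streaming(el$trace, estimator_config(window_size = w))
      if (out$status == "predicted") out$saved_time else NA
    })
    saved <- saved[!is.na(saved)]
    expect_true(all(diff(saved) <= 0))
  }
})
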