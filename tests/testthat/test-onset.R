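test_that("derivative is the backward difference over dt", {
  expect_equal(trace_derivative(amperogram(0:2, c(5, 3, 2))), c(-2, -1))
  expect_equal(trace_derivative(amperogram(0:9, rep(4, 10))), rep(0, 9))
  tr <- amperogram(seq(0, 2, by = 0.5), c(4, 3, 2.5, 2.25, 2.125))
  expect_equal(trace_derivative(tr), diff(tr$currents) / 0.5)
  # pure exponential: the most negative difference is the first one
  ex <- amperogram(0:30, 10 * exp(-0.2 * (0:30)) + 2)
  expect_equal(which.min(trace_derivative(ex)), 1L)
})

test_that("onset lands at the start of a clean decay after a plateau", {
  tr <- make_plateau_decay(100, A = 10, B = 0.1, C = 2)
  res <- find_onset(tr)
  expect_true(res$detected)
  # true decay begins at sample 101; first drop at 102
  expect_true(res$onset_index >= 101 && res$onset_index <= 103)
  expect_lt(res$derivative_at_onset, 0)
  expect_equal(res$restarts, 0L)
})

test_that("no onset on a rising signal; no restarts on a monotone decay", {
  up <- amperogram(0:49, seq(1, 5, length.out = 50))
  expect_false(find_onset(up)$detected)

  down <- amperogram(0:49, 10 * exp(-0.05 * (0:49)))
  res <- find_onset(down)
  expect_equal(res$restarts, 0L)
  expect_true(res$detected)
})

test_that("a spike re-arms the search and onset lands after it", {
  # plateau at 42, a 3-sample positive spike (48, 43, 46), then the decay:
  # the fall inside the spike creates a false candidate, the rise 43 -> 46
  # must discard it (restart), and the decay's own first interval undercuts
  # the spike's trailing edge
  plateau <- rep(42, 30)
  spike <- c(48, 43, 46)
  decay <- 30 * exp(-0.3 * (0:29)) + 12
  y <- c(plateau, spike, decay)
  tr <- amperogram(seq_along(y) - 1, y)
  res <- find_onset(tr)
  expect_true(res$detected)
  expect_gte(res$restarts, 1L)
  expect_gt(res$onset_index, 33L)  # strictly after the spike
  # oracle: the derivative argmin restricted to the post-spike region
  d <- diff(y)
  oracle <- which.min(replace(d, 1:33, Inf)) + 1L
  expect_equal(res$onset_index, oracle)
})

test_that("onset decisions are causal: prefixes give identical results", {
  set.seed(21)
  for (rep in 1:10) {
    g <- generate_trace(trace_spec(A = runif(1, 20, 80), B = runif(1, 0.08, 0.3),
                                   C = runif(1, 20, 60), seed = 100 + rep))
    f <- ema_filter(g$trace, 0.22)
    res <- find_onset(f)
    if (res$detected) {
      cut <- res$decided_index
      prefix <- amperogram(f$times[1:cut], f$currents[1:cut], dt = f$dt)
      res2 <- find_onset(prefix)
      expect_equal(res2[c("detected", "onset_index", "onset_time",
                          "derivative_at_onset", "restarts")],
                   res[c("detected", "onset_index", "onset_time",
                         "derivative_at_onset", "restarts")])
    }
  }
})

test_that("noiseless onsets are recovered within the confirmation horizon", {
  cfg <- onset_config()
  for (L in c(10, 40, 80, 120)) {
    for (B in c(0.02, 0.1, 0.5)) {
      tr <- make_plateau_decay(L, A = 30, B = B, C = 10, decay_n = 60)
      res <- find_onset(tr, cfg)
      expect_true(res$detected)
      expect_lte(abs(res$onset_index - (L + 1L)), cfg$confirm_k + 2L)
    }
  }
})
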