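# amperest

Real-time endpoint prediction for amperometric enzyme biosensor
measurements.

An amperometric biosensor reads the analyte concentration off the
*stabilized* current I∞ at the end of an enzymatic reaction — and waiting
for stabilization dominates the analysis time (around a minute per sample).
`amperest` predicts the final current early. The post-onset decay is modeled
as a one-phase exponential,

    I(t) = A·exp(−B·t) + C

with `t` counted from the onset of the decay: `A` is the span above the
asymptote (proportional to the analyte amount), `B` the reaction's decay
rate (1/s), and `C` the asymptote — the predicted I∞. The pipeline is
strictly causal, so it could run on the instrument during the measurement:

1. **EMA filter** — `A_n = α·M_n + (1−α)·A_{n−1}` (default α = 0.22,
   i.e. period p = 8 via α = 2/(p+1)) smooths injection noise;
2. **onset detection** — the minimum of the filtered signal's first
   derivative, confirmed causally, with restart logic that skips injection
   spikes;
3. **buffer** — 15 post-onset samples (seconds, at 1 Hz);
4. **fit** — a from-scratch Levenberg–Marquardt solver
   (`(JᵗJ + λI)δ = JᵗE`, λ starting at 0.1, adjustment factor 10) seeded by
   log-linearization;
5. **predict** — report `C` and stop; everything after `onset + window` is
   saved time.

The package also ships a synthetic amperogram generator with ground truth
(plateau, stochastic injection transient with spikes, exponential decay,
noise, automatic stabilization end) and sweep harnesses over the filter
constant and the buffer length, for evaluating the trade-offs the method
lives on. It is aimed at biosensor/instrumentation developers and at anyone
studying early-stopping estimators for exponential-settling signals.

## Worked example

```r
library(amperest)

# one synthetic measurement: span 30, rate 0.15/s, asymptote 25
g <- generate_trace(trace_spec(A = 30, B = 0.15, C = 25, seed = 42))
g$trace
#> <amperogram> 65 samples, dt = 1 s, t in [0, 64] s, current in [24.2, 61.1]

out <- run_streaming(g$trace, estimator_config())
out
#> <predicted> I_est = 24.01 (real 25.24, PE 4.86%), onset 20 s, saved 29 s
out$fit
#> <decay fit> A = 14.8768, B = 0.131401 /s, C = 24.0098 | SSE = 1.007, 4 iteration(s), converged
```

The 65-second analysis could have stopped after 35 s: the onset was
committed at 20 s, the buffer was full 15 s later, and the predicted
endpoint (24.0) is within 5% of the value the device eventually measured
(25.2). The fitted `A` is smaller than the generated span because the
detector commits a few samples after the true onset — by then part of the
span is already spent, which changes `A` but not the asymptote `C` being
predicted.

On a 200-trace cohort, the buffer-length trade-off looks like this:

```r
cohort <- generate_cohort(200, seed = 1)
sw <- sweep_window(cohort, windows = c(10, 15, 20, 25))
sw[, c("window_size", "no_algorithm", "mean_error_pct", "pe_lt10_pct", "mean_saved_s")]
#>   window_size no_algorithm mean_error_pct pe_lt10_pct mean_saved_s
#> 1          10            0       6.134412        86.0     25.88500
#> 2          15            0       2.250367        98.0     20.88500
#> 3          20            0       1.508343        99.5     15.88500
#> 4          25            8       1.309317       100.0     11.52083
```

Longer windows fit better but save less time, and at 25 samples some fast
reactions end before the buffer fills ("no algorithm"). Window 15 is the
operating point. Early stopping also makes the analysis duration far more
predictable:

```r
d <- duration_stats(run_cohort(cohort))
c(d$variance_s2, d$with_algorithm_variance_s2)
#> [1] 154.13364  24.69789
```

## Command line

A thin CLI over the same functions lives in `inst/cli/amperest`:

```sh
Rscript inst/cli/amperest simulate --n 200 --seed 7 --out traces/
Rscript inst/cli/amperest predict --trace traces/trace_0001.csv
Rscript inst/cli/amperest sweep-window --cohort traces/ --windows 10,15,20,25 --out table.csv
```

Configuration (YAML, overlaid on the defaults; unknown keys are refused):

```yaml
filter: {p: 8}            # or alpha: 0.22
estimator: {window_size: 15}
lm: {lambda0: 0.1, factor: 10}
```

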