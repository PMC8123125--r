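# Fixtures and independent oracles shared across the suite.

# Noiseless post-onset window sampled from the decay model.
make_window <- function(A, B, C, len = 15L, dt = 1) {
  t <- seq(0, by = dt, length.out = len)
  fit_window(t, A * exp(-B * t) + C)
}

# Plateau + clean decay trace; decay starts at sample index plateau_n + 1
# with the plateau value (continuity), so the first drop is one sample later.
make_plateau_decay <- function(plateau_n, A, B, C, decay_n = 40L, dt = 1) {
  y <- c(rep(A + C, plateau_n),
         A * exp(-B * seq(0, by = dt, length.out = decay_n)) + C)
  amperogram(seq(0, by = dt, length.out = plateau_n + decay_n), y, dt = dt)
}

# Brute-force SSE minimum over an n^3 grid of (A, B, C) boxes around the data
# range. The per-point SSE is expanded algebraically so the full enumeration
# stays cheap; it is exactly sum((y - A*exp(-B*t) - C)^2) at every grid node.
grid_sse_min <- function(window, n = 50L) {
  y <- window$y
  t <- window$t
  span <- max(y) - min(y)
  A_grid <- seq(0.1 * span, 3 * span, length.out = n)
  B_grid <- seq(0.005, 1, length.out = n)
  C_grid <- seq(min(y) - span, min(y) + span, length.out = n)
  S_yy <- sum(y * y)
  S_y <- sum(y)
  m <- length(y)
  best <- Inf
  for (B in B_grid) {
    e <- exp(-B * t)
    S_e <- sum(e)
    S_ee <- sum(e * e)
    S_ye <- sum(y * e)
    # SSE(A, C) = S_yy - 2A S_ye - 2C S_y + A^2 S_ee + 2AC S_e + C^2 m
    sse <- outer(A_grid, C_grid, function(A, C) {
      S_yy - 2 * A * S_ye - 2 * C * S_y + A^2 * S_ee + 2 * A * C * S_e + C^2 * m
    })
    best <- min(best, min(sse))
  }
  best
}
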