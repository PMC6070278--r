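# Minimal adaptive Dormand-Prince 5(4) integrator.
#
# No ODE solver package is assumed; the systems integrated here are tiny
# (<= 8 state variables) and only moderately stiff, so an embedded explicit
# pair with PI step control is adequate.

rk45 <- function(f, y0, t0, t1, rtol = 1e-9, atol = 1e-12,
                 max_steps = 5e6, save_at = NULL) {
  # Dormand-Prince coefficients
  c2 <- 1/5; c3 <- 3/10; c4 <- 4/5; c5 <- 8/9
  a21 <- 1/5
  a31 <- 3/40; a32 <- 9/40
  a41 <- 44/45; a42 <- -56/15; a43 <- 32/9
  a51 <- 19372/6561; a52 <- -25360/2187; a53 <- 64448/6561; a54 <- -212/729
  a61 <- 9017/3168; a62 <- -355/33; a63 <- 46732/5247; a64 <- 49/176
  a65 <- -5103/18656
  b1 <- 35/384; b3 <- 500/1113; b4 <- 125/192; b5 <- -2187/6784; b6 <- 11/84
  e1 <- 71/57600; e3 <- -71/16695; e4 <- 71/1920; e5 <- -17253/339200
  e6 <- 22/525; e7 <- -1/40

  y <- y0
  t <- t0
  h <- (t1 - t0) * 1e-4
  out_t <- numeric(0)
  out_y <- NULL
  save_at <- sort(save_at[save_at > t0 & save_at <= t1])
  next_save <- if (length(save_at)) save_at[1] else Inf
  save_idx <- 1L
  k1 <- f(t, y)
  steps <- 0L
  while (t < t1) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("rk45: step budget exhausted at t = ", signif(t, 6), call. = FALSE)
    h <- min(h, t1 - t, next_save - t)
    if (h <= .Machine$double.eps * max(1, abs(t)))
      h <- .Machine$double.eps * max(1, abs(t)) * 2
    k2 <- f(t + c2 * h, y + h * a21 * k1)
    k3 <- f(t + c3 * h, y + h * (a31 * k1 + a32 * k2))
    k4 <- f(t + c4 * h, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
    k5 <- f(t + c5 * h, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
    k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                              a65 * k5))
    y5 <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
    k7 <- f(t + h, y5)
    err_vec <- h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean((err_vec / sc)^2))
    if (!is.finite(err)) { h <- h / 10; next }
    if (err <= 1) {
      t <- t + h
      y <- y5
      k1 <- k7                       # FSAL
      if (t >= next_save - 1e-12 * max(1, abs(t))) {
        out_t <- c(out_t, t)
        out_y <- rbind(out_y, y)
        save_idx <- save_idx + 1L
        next_save <- if (save_idx <= length(save_at)) save_at[save_idx] else Inf
      }
    }
    fac <- 0.9 * (1 / max(err, 1e-10))^0.2
    h <- h * min(5, max(0.2, fac))
  }
  list(t = t, y = y, save_t = out_t, save_y = out_y, steps = steps)
}
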