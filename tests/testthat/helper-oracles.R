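# Independent oracles and small simulators shared across tests.

# Brute-force windowed Fisher information: composes the speed/acceleration
# definitions by hand, with derivatives from an explicitly solved
# three-point interpolating parabola (Vandermonde solve), trapezoid by hand.
# Deliberately written straight-line, independent of the package's stencil.
fisher_oracle <- function(times, values, T_win, step, eps) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  n <- length(times)
  m <- ncol(values)
  d1 <- d2 <- matrix(NA_real_, n, m)
  for (i in 2:(n - 1)) {
    tt <- times[(i - 1):(i + 1)]
    V <- cbind(1, tt, tt^2)
    for (j in 1:m) {
      co <- solve(V, values[(i - 1):(i + 1), j])   # y = c0 + c1 t + c2 t^2
      d1[i, j] <- co[2] + 2 * co[3] * times[i]
      d2[i, j] <- 2 * co[3]
    }
  }
  sp <- sqrt(rowSums(d1^2))
  sa <- rowSums(d1 * d2) / sp
  starts <- seq(times[1], times[n] - T_win, by = step)
  fi <- vapply(starts, function(w0) {
    idx <- which(times >= w0 & times <= w0 + T_win &
                   is.finite(sp) & is.finite(sa))
    keep <- idx[sp[idx] >= eps]
    g <- sa[keep]^2 / sp[keep]^4
    tt <- times[keep]
    acc <- 0
    for (q in seq_len(length(tt) - 1))
      acc <- acc + (g[q] + g[q + 1]) * (tt[q + 1] - tt[q]) / 2
    acc / T_win
  }, numeric(1))
  list(centers = starts + T_win / 2, fi = fi)
}

# AR(1) simulator with a possibly time-varying innovation sd.
sim_ar1 <- function(n, phi = 0.5, sigma = 1, seed = 42) {
  set.seed(seed)
  s <- rep(sigma, length.out = n)
  x <- numeric(n)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1, 0, s[i])
  x
}

# Build a fisher_series by hand for detector tests.
make_fisher_series <- function(centers, fi) {
  structure(list(centers = centers, fi = fi,
                 window_length = NA_real_, step = NA_real_,
                 eps_speed = NA_real_,
                 dropped_fraction = rep(0, length(centers))),
            class = "fisher_series")
}

expect_close <- function(x, y, tol) expect_true(all(abs(x - y) <= tol))
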