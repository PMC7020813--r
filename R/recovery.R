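#' Normalized difference moisture index
#'
#' NDMI = (NIR - SWIR1) / (NIR + SWIR1), tracking canopy moisture content:
#' low for bare soil and thin canopies, high for fully developed ones.
#'
#' @param nir near-infrared reflectance (>= 0).
#' @param swir1 shortwave-infrared reflectance (>= 0).
#' @return NDMI in `[-1, 1]`, vectorized.
#' @export
ndmi <- function(nir, swir1) {
  if (any(nir < 0) || any(swir1 < 0)) stop("reflectances must be nonnegative")
  denom <- nir + swir1
  if (any(denom == 0)) stop("nir + swir1 must be nonzero")
  (nir - swir1) / denom
}

#' Fit a seasonal harmonic baseline model
#'
#' y_t = alpha + sum_{j=1..J} gamma_j * sin(2*pi*j*t/f + delta_j) + eps_t,
#' the standard harmonic-regression description of an undisturbed seasonal
#' signal (j = 1 is the annual cycle).  The phase-shifted sines are fitted
#' through the equivalent linear sin/cos basis, so the fit is closed-form
#' ordinary least squares: gamma_j = sqrt(a_j^2 + b_j^2),
#' delta_j = atan2(b_j, a_j).
#'
#' @param y numeric response (one spectral band or index).
#' @param times observation times, same units as `f`'s denominator (e.g.
#'   months with `f = 12` observations per year).
#' @param f known number of observations per year.
#' @param J number of harmonics (default 3).
#' @return an object of class `harmonic_model`: `intercept`, `amplitudes`,
#'   `phases` (in `[-pi, pi)`), `frequency`, `J`, `residual_sd`.
#' @export
fit_harmonic <- function(y, times, f = 12, J = 3L) {
  J <- as.integer(J)
  n <- length(y)
  if (length(times) != n) stop("y and times must have equal length")
  npar <- 2L * J + 1L
  if (n < npar + 1L) stop("need at least ", npar + 1L, " observations to fit ",
                          J, " harmonics")
  X <- matrix(1, n, npar)
  for (j in seq_len(J)) {
    w <- 2 * pi * j * times / f
    X[, 2L * j] <- sin(w)
    X[, 2L * j + 1L] <- cos(w)
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  a <- cf[seq(2L, npar, by = 2L)]
  b <- cf[seq(3L, npar, by = 2L)]
  gam <- sqrt(a^2 + b^2)
  del <- atan2(b, a)
  del[del >= pi] <- del[del >= pi] - 2 * pi
  rsd <- if (n > npar) sqrt(sum(fit$residuals^2) / (n - npar)) else 0
  structure(list(intercept = unname(cf[1L]), amplitudes = unname(gam),
                 phases = unname(del), frequency = f, J = J,
                 residual_sd = rsd),
            class = "harmonic_model")
}

#' Evaluate a harmonic model
#'
#' @param model a [harmonic_model].
#' @param times times at which to predict, in the convention used when
#'   fitting.
#' @return fitted values.
#' @export
predict_harmonic <- function(model, times) {
  y <- rep(model$intercept, length(times))
  for (j in seq_len(model$J)) {
    y <- y + model$amplitudes[j] *
      sin(2 * pi * j * times / model$frequency + model$phases[j])
  }
  y
}

#' Multi-band Euclidean deviation from harmonic baselines
#'
#' D_t = sqrt( sum_{i=1..k} (yhat_it - y_it)^2 ): at each time, the Euclidean
#' distance between the observed band vector and the values the per-band
#' harmonic baseline models predict.
#'
#' @param obs an [eco_ts] whose k variables are the observed bands, aligned
#'   on identical times.
#' @param models list of k [harmonic_model]s, one per band, in column order.
#' @return an object of class `deviation_series`: `times`, `D`, `k`.
#' @export
spectral_distance <- function(obs, models) {
  k <- ncol(obs$values)
  if (length(models) != k) stop("need one model per band (", k, ")")
  if (has_gaps(obs)) stop("bands have gaps; fill them first")
  dev2 <- numeric(length(obs$times))
  for (i in seq_len(k)) {
    yhat <- predict_harmonic(models[[i]], obs$times)
    dev2 <- dev2 + (yhat - obs$values[, i])^2
  }
  structure(list(times = obs$times, D = sqrt(dev2), k = k),
            class = "deviation_series")
}

#' Spectral-recovery time after a disturbance
#'
#' The spectral-resilience reading of a deviation series: the threshold is
#' the `q`-quantile (default 0.95) of the pre-disturbance baseline
#' deviations; the recovery duration is the first post-disturbance time at
#' which D stays below the threshold for `m` consecutive observations, minus
#' the disturbance time.
#'
#' @param dev a `deviation_series`.
#' @param disturbance_time time of the disturbance.
#' @param baseline length-2 interval `c(t0, t1)` preceding the disturbance,
#'   containing at least 10 observations.
#' @param q baseline quantile for the threshold (default 0.95).
#' @param m consecutive below-threshold observations required (default 3).
#' @return recovery duration in time units, or `NA` if D never recovers.
#' @export
recovery_time <- function(dev, disturbance_time, baseline, q = 0.95, m = 3L) {
  if (length(baseline) != 2L || baseline[1L] >= baseline[2L])
    stop("baseline must be an increasing interval c(t0, t1)")
  if (baseline[2L] > disturbance_time)
    stop("baseline interval must precede the disturbance time")
  in_b <- dev$times >= baseline[1L] & dev$times <= baseline[2L]
  if (sum(in_b) < 10L)
    stop("baseline too short: need at least 10 observations, have ", sum(in_b))
  threshold <- stats::quantile(dev$D[in_b], q, names = FALSE)
  post <- which(dev$times > disturbance_time)
  if (length(post) < m) return(NA_real_)
  ok <- dev$D[post] < threshold
  for (i in seq_len(length(post) - m + 1L)) {
    if (all(ok[i:(i + m - 1L)]))
      return(dev$times[post[i]] - disturbance_time)
  }
  NA_real_
}
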