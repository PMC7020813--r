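#' Phase-space derivatives by the three-point difference scheme
#'
#' First and second time derivatives of every state variable at each interior
#' point, using the non-uniform three-point stencil: fit the parabola through
#' (t - dt_p, t, t + dt_a) and differentiate it at the centre.  The scheme is
#' exact for quadratic signals under arbitrary spacing and reduces to central
#' differences when the spacing ratio alpha = dt_p/dt_a equals 1.  Endpoints
#' have no bracketing pair and are flagged `NA`.
#'
#' @param ts a gap-free [eco_ts] with at least 3 points.
#' @return an object of class `eco_derivatives`: `times`, `d1` and `d2`
#'   (n x m matrices, `NA` at endpoints) and `alpha` (per-point spacing
#'   ratio dt_p/dt_a).
#' @export
phase_derivatives <- function(ts) {
  if (has_gaps(ts)) stop("series has gaps; fill them first")
  n <- n_obs(ts)
  if (n < 3L) stop("need at least 3 points for the three-point scheme")
  tm <- ts$times
  i <- 2:(n - 1L)
  h1 <- tm[i] - tm[i - 1L]          # dt_p, spacing to previous point
  h2 <- tm[i + 1L] - tm[i]          # dt_a, spacing to next point
  w_prev1 <- -h2 / (h1 * (h1 + h2))
  w_cent1 <- (h2 - h1) / (h1 * h2)
  w_next1 <- h1 / (h2 * (h1 + h2))
  w_prev2 <- 2 / (h1 * (h1 + h2))
  w_cent2 <- -2 / (h1 * h2)
  w_next2 <- 2 / (h2 * (h1 + h2))
  m <- ncol(ts$values)
  d1 <- d2 <- matrix(NA_real_, n, m, dimnames = list(NULL, ts$names))
  for (j in seq_len(m)) {
    x <- ts$values[, j]
    d1[i, j] <- w_prev1 * x[i - 1L] + w_cent1 * x[i] + w_next1 * x[i + 1L]
    d2[i, j] <- w_prev2 * x[i - 1L] + w_cent2 * x[i] + w_next2 * x[i + 1L]
  }
  alpha <- rep(NA_real_, n)
  alpha[i] <- h1 / h2
  structure(list(times = tm, d1 = d1, d2 = d2, alpha = alpha),
            class = "eco_derivatives")
}

#' Tangential speed along the phase-space path
#'
#' s'(t) = sqrt(sum_i (dx_i/dt)^2), the speed of the phase point along its
#' trajectory.
#'
#' @param d an `eco_derivatives` object from [phase_derivatives].
#' @return numeric vector, `NA` at endpoints.
#' @export
tangential_speed <- function(d) {
  sqrt(rowSums(d$d1^2))
}

#' Tangential acceleration along the phase-space path
#'
#' s''(t) = (1/s') * sum_i (dx_i/dt)(d^2 x_i/dt^2), the scalar acceleration
#' tangent to the trajectory.  Undefined (`NA`) where the speed vanishes.
#'
#' @param d an `eco_derivatives` object.
#' @return numeric vector, `NA` at endpoints and where s' = 0.
#' @export
tangential_acceleration <- function(d) {
  sp <- tangential_speed(d)
  num <- rowSums(d$d1 * d$d2)
  out <- num / sp
  out[!is.na(sp) & sp == 0] <- NA_real_
  out
}

dominant_period <- function(x, times) {
  # periodogram of the (demeaned) first variable; period of the peak
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  nf <- floor(n / 2)
  if (nf < 2L) stop("series too short to pick a dominant period")
  k <- which.max(p[2:(nf + 1L)])    # skip the zero frequency
  dt <- mean(diff(times))
  n * dt / k
}

#' Sliding-window Fisher information of a trajectory
#'
#' For each window of length `window_length` (the cycle period T), computes
#' I = (1/T) * integral of s''(t)^2 / s'(t)^4 dt by the trapezoid rule over
#' the window's interior samples.  High, steady Fisher information signals a
#' stable regime (low variability); drops flag regime shifts.  Because the
#' integrand diverges where the speed s' vanishes (every turning point of a
#' 1-D signal), points with s' below `eps_speed` are excluded and counted in
#' `dropped_fraction`.
#'
#' @param ts a gap-free [eco_ts].
#' @param window_length window length T in time units; `NULL` picks the
#'   dominant period of the first variable from its periodogram.
#' @param step window advance in time units; `NULL` uses one sampling step.
#' @param eps_speed absolute numeric floor on s'; `NULL` (default) floors at
#'   `eps_frac` times each window's maximum speed.  The per-window relative
#'   floor keeps the estimator scale-equivariant (fi scales as 1/c^2 when the
#'   trajectory is scaled by c) and discards the turning-point neighbourhoods
#'   whose 1/s'^4 blow-up is a discretization artifact, not information.
#' @param eps_frac fraction of the window's maximum speed used as the floor
#'   when `eps_speed` is `NULL` (default 0.1; effectively no floor at 1e-6
#'   makes windowed fi on rough noise heavy-tailed to the point of
#'   uselessness).
#' @param normalize min-max normalize each variable to `[0, 1]` before
#'   differencing (default `TRUE`): the speed sums squared derivatives across
#'   variables, which is meaningless across heterogeneous units.
#' @return an object of class `fisher_series`: `centers` (window centre
#'   times), `fi` (Fisher information, `NA` where every point in the window
#'   fell below the speed floor), `window_length`, `step`, `eps_speed`,
#'   `dropped_fraction`.
#' @export
fisher_information <- function(ts, window_length = NULL, step = NULL,
                               eps_speed = NULL, eps_frac = 0.1,
                               normalize = TRUE) {
  if (has_gaps(ts)) stop("series has gaps; fill them first")
  if (normalize) {
    vals <- ts$values
    for (j in seq_len(ncol(vals))) {
      r <- range(vals[, j])
      if (diff(r) > 0) vals[, j] <- (vals[, j] - r[1L]) / (r[2L] - r[1L])
      else vals[, j] <- 0
    }
    ts <- eco_ts(ts$times, vals, names = ts$names, meta = ts$meta)
  }
  tm <- ts$times
  if (is.null(window_length))
    window_length <- dominant_period(ts$values[, 1L], tm)
  if (window_length <= 0) stop("window_length must be positive")
  if (is.null(step)) step <- stats::median(diff(tm))
  if (step <= 0) stop("step must be positive")

  d <- phase_derivatives(ts)
  sp <- tangential_speed(d)
  sa <- tangential_acceleration(d)

  starts <- seq(tm[1L], tm[length(tm)] - window_length, by = step)
  if (!length(starts)) stop("window_length exceeds the series span")
  first_n <- sum(tm >= starts[1L] & tm <= starts[1L] + window_length)
  if (first_n < 8L)
    stop("window_length must cover at least 8 samples (covers ", first_n, ")")

  centers <- starts + window_length / 2
  fi <- dropped <- rep(NA_real_, length(starts))
  for (w in seq_along(starts)) {
    idx <- which(tm >= starts[w] & tm <= starts[w] + window_length &
                   is.finite(sp) & is.finite(sa))
    if (length(idx) < 2L) { dropped[w] <- 1; next }
    eps <- if (is.null(eps_speed)) eps_frac * max(sp[idx]) else eps_speed
    keep <- idx[sp[idx] >= eps]
    dropped[w] <- 1 - length(keep) / length(idx)
    if (length(keep) < 2L) next     # fi stays flagged undefined
    g <- sa[keep]^2 / sp[keep]^4
    fi[w] <- trapz(tm[keep], g) / window_length
  }
  structure(list(centers = centers, fi = fi,
                 window_length = window_length, step = step,
                 eps_speed = if (is.null(eps_speed)) NA_real_ else eps_speed,
                 dropped_fraction = dropped),
            class = "fisher_series")
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' @export
print.fisher_series <- function(x, ...) {
  cat(sprintf("<fisher_series> %d windows, T = %g, step = %g\n",
              length(x$centers), x$window_length, x$step))
  invisible(x)
}

#' Detect Fisher-information recovery after a disturbance
#'
#' A resilient system's Fisher information returns to (or above) its
#' pre-disturbance value.  This detector takes the baseline mean and sd of
#' `fi` over a pre-disturbance interval and reports the first
#' post-disturbance window centre from which `fi` stays at or above
#' `mean_b - k * sd_b` for `m` consecutive windows.
#'
#' @param fs a `fisher_series`.
#' @param baseline length-2 numeric interval `c(t0, t1)` strictly preceding
#'   the disturbance and containing at least 5 windows.
#' @param disturbance_time time of the disturbance event.
#' @param k band half-width in baseline standard deviations (default 2).
#' @param m number of consecutive windows required in the band (default 3).
#' @return recovery time (a window centre), or `NA` if `fi` never re-enters
#'   the band.
#' @export
detect_recovery <- function(fs, baseline, disturbance_time, k = 2, m = 3) {
  if (length(baseline) != 2L || baseline[1L] >= baseline[2L])
    stop("baseline must be an increasing interval c(t0, t1)")
  if (baseline[2L] > disturbance_time)
    stop("baseline interval must precede the disturbance time")
  in_b <- fs$centers >= baseline[1L] & fs$centers <= baseline[2L] &
    is.finite(fs$fi)
  if (sum(in_b) < 5L)
    stop("baseline too short: need at least 5 windows, have ", sum(in_b))
  mean_b <- mean(fs$fi[in_b])
  sd_b <- stats::sd(fs$fi[in_b])
  lower <- mean_b - k * sd_b
  post <- which(fs$centers > disturbance_time)
  if (length(post) < m) return(NA_real_)
  ok <- is.finite(fs$fi[post]) & fs$fi[post] >= lower
  for (i in seq_len(length(post) - m + 1L)) {
    if (all(ok[i:(i + m - 1L)])) return(fs$centers[post[i]])
  }
  NA_real_
}
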