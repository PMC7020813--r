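#' Disturbance scenario for the seasonal generator
#'
#' Describes an abrupt disturbance (a wildfire-like event) at a given time:
#' an immediate drop of `drop` times the seasonal mean, an exponential
#' return at `recovery_rate`, and an asymptotic deficit `permanent_offset`
#' (0 = full recovery).  The deficit fraction at time t >= time is
#' `permanent_offset + (drop - permanent_offset) * exp(-recovery_rate * (t - time))`,
#' so it equals `drop` at the event and tends to `permanent_offset`.
#'
#' @param time event time (same units as the series times).
#' @param drop fraction of the seasonal mean removed at the event, `[0, 1]`.
#' @param recovery_rate exponential return rate per time unit (>= 0).
#' @param permanent_offset asymptotic deficit fraction, `0 <= offset <= drop`.
#' @return an object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(time, drop, recovery_rate, permanent_offset = 0) {
  if (drop < 0 || drop > 1) stop("drop must lie in [0, 1]")
  if (recovery_rate < 0) stop("recovery_rate must be nonnegative")
  if (permanent_offset < 0 || permanent_offset > drop)
    stop("permanent_offset must lie in [0, drop]")
  structure(list(time = time, drop = drop, recovery_rate = recovery_rate,
                 permanent_offset = permanent_offset),
            class = "disturbance_spec")
}

deficit_fraction <- function(dist, times) {
  out <- numeric(length(times))
  post <- times >= dist$time
  out[post] <- dist$permanent_offset +
    (dist$drop - dist$permanent_offset) *
    exp(-dist$recovery_rate * (times[post] - dist$time))
  out
}

#' Generate a seasonal series with an abrupt disturbance
#'
#' Synthetic stand-in for a monthly vegetation-index (NDVI-like) record over
#' a wildfire: a harmonic seasonal signal (intercept `alpha`, harmonic
#' amplitudes `gammas` and phases `deltas`, `f` observations per year) minus
#' a disturbance deficit, plus Gaussian observation noise.  The deficit is
#' applied to the deterministic component before noise, so the generator
#' truth stored in `meta$truth` is exact.  Times are 0, 1, ..., n-1 in
#' observation units (months for `f = 12`).
#'
#' @param n number of observations (must be >= 2*f, two full years).
#' @param f observations per year (default 12).
#' @param alpha seasonal mean level.
#' @param gammas harmonic amplitudes (length J).
#' @param deltas harmonic phases in radians (length J).
#' @param dist a [disturbance_spec], or `NULL` for no disturbance.
#' @param sigma sd of the additive Gaussian noise.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param var_name name for the generated variable (default `"NDVI"`).
#' @return an [eco_ts] with `meta$truth = list(deficit, clean, dist)`:
#'   the absolute deficit trajectory, the noise-free disturbed signal and
#'   the disturbance spec.
#' @export
gen_seasonal_disturbance <- function(n, f = 12, alpha = 0.5,
                                     gammas = c(0.25, 0.05, 0.02),
                                     deltas = c(-1.5, 0.5, 0),
                                     dist = NULL, sigma = 0.02, seed = 1L,
                                     var_name = "NDVI") {
  if (n < 2 * f) stop("need at least two full years of observations (n >= 2f)")
  if (length(gammas) != length(deltas))
    stop("gammas and deltas must have equal length")
  times <- seq(0, n - 1)
  y <- rep(alpha, n)
  for (j in seq_along(gammas))
    y <- y + gammas[j] * sin(2 * pi * j * times / f + deltas[j])
  deficit <- if (is.null(dist)) numeric(n) else alpha * deficit_fraction(dist, times)
  clean <- y - deficit
  if (!is.null(seed)) set.seed(seed)
  obs <- clean + stats::rnorm(n, 0, sigma)
  eco_ts(times, obs, names = var_name,
         meta = list(truth = list(deficit = deficit, clean = clean,
                                  dist = dist),
                     f = f, alpha = alpha, gammas = gammas, deltas = deltas,
                     sigma = sigma, seed = seed))
}

#' Generate 1/f^beta colored noise by spectral synthesis
#'
#' Shapes a complex Gaussian spectrum by f^(-beta/2) (random phases),
#' inverse-transforms and standardizes to mean 0, sd 1.  beta = 0 gives
#' white noise, 1 pink, 2 Brownian-like fluctuations; the target slope is
#' exact in expectation with no burn-in.
#'
#' @param n sequence length.
#' @param beta target spectral exponent (>= 0).
#' @param seed integer seed.
#' @return standardized numeric sequence of length n.
#' @export
gen_colored_noise <- function(n, beta, seed = 1L) {
  if (n < 8L) stop("n too small")
  if (!is.null(seed)) set.seed(seed)
  nf <- n %/% 2L
  freq <- seq_len(nf) / n
  amp <- freq^(-beta / 2)
  re <- stats::rnorm(nf); im <- stats::rnorm(nf)
  half <- complex(real = re, imaginary = im) * amp
  # Hermitian assembly around a zero DC bin so the inverse transform is real
  spec <- complex(real = rep(0, n))
  spec[2:(nf + 1L)] <- half
  if (n %% 2L == 0L) spec[nf + 1L] <- complex(real = re[nf] * amp[nf])
  spec[(nf + 2L):n] <- Conj(rev(spec[2:(n - nf)]))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a random Boolean network
#'
#' Classic Kauffman NK construction: each node receives K distinct inputs
#' chosen uniformly at random and a random truth table whose entries are 1
#' with probability `bias`.  The initial state is uniform random.
#'
#' @param N number of nodes.
#' @param K in-degree per node, `0 <= K <= N`.
#' @param bias probability of a 1 in each truth-table entry (default 0.5).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return an object of class `boolean_network`: `N`, `K`, `inputs`
#'   (N x K matrix of source nodes), `tables` (N x 2^K matrix of 0/1),
#'   `state` (length-N 0/1 vector).
#' @export
gen_rbn <- function(N, K, bias = 0.5, seed = 1L) {
  N <- as.integer(N); K <- as.integer(K)
  if (K > N) stop("K cannot exceed N")
  if (K < 0L) stop("K must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  inputs <- matrix(0L, N, K)
  for (i in seq_len(N)) if (K > 0L) inputs[i, ] <- sample.int(N, K)
  tables <- matrix(stats::rbinom(N * 2^K, 1L, bias), N, 2^K)
  state <- stats::rbinom(N, 1L, 0.5)
  structure(list(N = N, K = K, inputs = inputs, tables = tables,
                 state = state),
            class = "boolean_network")
}

#' Generate a flow network fixture
#'
#' Four archetypes for exercising ascendancy: `"independent"` (rank-one
#' flows, AMI exactly 0), `"diagonal"` (a permutation network with equal
#' flows, AMI = log2 n), `"chain"` (equal flows i -> i+1) and `"random"`
#' (positive uniform flows).
#'
#' @param n compartments.
#' @param structure one of `"independent"`, `"chain"`, `"diagonal"`,
#'   `"random"`.
#' @param seed integer seed (used by `"independent"` and `"random"`).
#' @return a [flow_network].
#' @export
gen_flow_network <- function(n, structure = c("independent", "chain",
                                              "diagonal", "random"),
                             seed = 1L) {
  structure_ <- match.arg(structure)
  if (!is.null(seed)) set.seed(seed)
  f <- switch(structure_,
    independent = {
      u <- stats::runif(n, 0.5, 1.5); v <- stats::runif(n, 0.5, 1.5)
      outer(u, v)
    },
    chain = {
      m <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) m[i, i + 1L] <- 1
      m
    },
    diagonal = {
      m <- matrix(0, n, n)
      perm <- sample.int(n)
      m[cbind(seq_len(n), perm)] <- 1
      m
    },
    random = matrix(stats::runif(n * n, 0.1, 1), n, n)
  )
  flow_network(f)
}
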