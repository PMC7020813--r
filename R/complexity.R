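#' Emergence: normalized Shannon information
#'
#' Emergence E is Shannon information normalized onto `[0, 1]` by the
#' alphabet size: E = -sum(p_k log p_k) / log(base_K).  E = 1 for the uniform
#' distribution, 0 for a point mass.  The normalization makes the logarithm
#' base irrelevant; base 2 is used internally.
#'
#' @param p nonnegative probability vector summing to 1 (tolerance 1e-9).
#' @param base_K declared alphabet size (>= 2 and >= the observed support);
#'   defaults to `length(p)`.  Unobserved-but-possible states carry
#'   information about order, so the declared alphabet, not the observed
#'   support, sets the scale.
#' @return emergence E in `[0, 1]`.
#' @export
emergence <- function(p, base_K = length(p)) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  if (base_K < 2) stop("base_K must be at least 2")
  if (base_K < sum(p > 0)) stop("base_K smaller than the observed support")
  pp <- p[p > 0]
  -sum(pp * log2(pp)) / log2(base_K)
}

#' Emergence, self-organization and complexity
#'
#' Self-organization S = 1 - E is the increase-of-order complement of
#' emergence; complexity C = 4*E*S peaks (C = 1) at the balance point
#' E = S = 0.5 and vanishes at both extremes of pure order and pure noise.
#'
#' @param E emergence in `[0, 1]`.
#' @return an object of class `complexity_triple`: named numeric
#'   `c(E =, S =, C =)`.
#' @export
complexity_triple <- function(E) {
  if (E < -1e-12 || E > 1 + 1e-12) stop("E must lie in [0, 1]")
  E <- min(max(E, 0), 1)
  S <- 1 - E
  structure(c(E = E, S = S, C = 4 * E * S), class = "complexity_triple")
}

#' Permutation entropy of a sequence
#'
#' Bandt-Pompe ordinal patterns: each window of `order` values at lag `delay`
#' is mapped to the permutation that sorts it (ties broken by temporal index,
#' the standard stable convention), and emergence is the Shannon entropy of
#' the pattern distribution normalized by log(order!).  Invariant under any
#' strictly monotone increasing transform of the data.
#'
#' @param x numeric sequence.
#' @param order pattern length d, typically 3 to 7.
#' @param delay lag between pattern elements (default 1).
#' @return normalized permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  d <- as.integer(order)
  tau <- as.integer(delay)
  n <- length(x)
  if (d < 2L) stop("order must be at least 2")
  if (n < d) stop("sequence shorter than the pattern order")
  n_win <- n - (d - 1L) * tau
  if (n_win < 1L) stop("sequence too short for this order/delay")
  keys <- vapply(seq_len(n_win), function(i) {
    w <- x[i + (0:(d - 1L)) * tau]
    paste(order(w, seq_along(w)), collapse = ".")
  }, character(1))
  p <- tabulate(factor(keys)) / n_win
  pp <- p[p > 0]
  -sum(pp * log2(pp)) / log2(factorial(d))
}

#' Complexity triple of a binary sequence
#'
#' Emergence from the (p0, p1) symbol frequencies with a two-letter alphabet,
#' then C = 4*E*(1-E).  Used per node on Boolean-network state trajectories.
#'
#' @param x vector of 0/1 (or logical) values.
#' @return a [complexity_triple].
#' @export
binary_complexity <- function(x) {
  x <- as.integer(as.logical(x))
  p1 <- mean(x)
  p <- c(1 - p1, p1)
  complexity_triple(emergence(p, base_K = 2))
}

welch_psd <- function(x, seg_frac = 8L, overlap = 0.5) {
  # Welch periodogram: Hann window, segments of length n/seg_frac, 50%
  # overlap, per-segment mean removal.  Returns frequencies in cycles/sample.
  n <- length(x)
  nseg <- floor(n / seg_frac)
  if (nseg < 16L) stop("series too short for the Welch periodogram")
  hop <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  wnorm <- sum(win^2)
  nf <- floor(nseg / 2)
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2 / wnorm
    psd <- psd + p[2:(nf + 1L)]
  }
  list(freq = seq_len(nf) / nseg, psd = psd / length(starts))
}

#' Spectral exponent beta of 1/f^beta fluctuations
#'
#' Estimates the power-law exponent of the power spectral density,
#' S(f) ~ 1/f^beta, as minus the ordinary-least-squares slope of log power
#' versus log frequency.  The spectrum is a Welch periodogram (Hann window,
#' segment length n/8, 50% overlap, per-segment mean removal) and the fit
#' uses the central band: the 2 lowest frequencies are excluded (leakage)
#' and so is the top eighth (rolloff near Nyquist).  beta ~ 0 is white
#' noise, ~ 1 pink (the criticality fingerprint), ~ 2 Brownian.
#'
#' @param x numeric sequence, length >= 512.
#' @return estimated spectral exponent beta.
#' @export
spectral_exponent <- function(x) {
  if (length(x) < 512L) stop("need at least 512 samples")
  if (diff(range(x)) == 0) stop("constant input has no spectrum")
  w <- welch_psd(x - mean(x))
  nf <- length(w$freq)
  keep <- seq.int(3L, floor(nf * 7 / 8))
  fit <- stats::lsfit(log10(w$freq[keep]), log10(w$psd[keep]))
  -unname(fit$coefficients[2L])
}

#' Classify a spectral exponent into a noise archetype
#'
#' Nearest of the three archetypes white (beta ~ 0), pink (~ 1) and Brownian
#' (~ 2), provided the estimate lies within 0.5 of it; `"other"` otherwise.
#'
#' @param beta estimated spectral exponent.
#' @return one of `"white"`, `"pink"`, `"brown"`, `"other"`.
#' @export
classify_noise <- function(beta) {
  arche <- c(white = 0, pink = 1, brown = 2)
  d <- abs(beta - arche)
  if (min(d) <= 0.5) names(arche)[which.min(d)] else "other"
}
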