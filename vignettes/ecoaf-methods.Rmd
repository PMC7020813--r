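---
title: "Methods: information-theoretic indicators of ecosystem stability and antifragility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-theoretic indicators of ecosystem stability and antifragility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoaf)
```

## Scope and model

`ecoaf` quantifies how an ecosystem's condition responds to disturbance,
using a family of information-theoretic indicators that share one premise:
the observable record — a multivariate time series of state variables such
as a vegetation index, or a matrix of inter-compartment flows — carries
enough structure to diagnose stability, resilience and, beyond them,
*antifragility* (benefiting from variability). The package implements six
indicator families and the synthetic generators needed to exercise them on
realistic inputs:

1. **Sliding-window Fisher information** of a phase-space trajectory,
2. **Emergence / self-organization / complexity** (E, S, C) from discrete
   and permutation entropy,
3. **Fragility scoring** `-ΔC·|Δx|` with a random-Boolean-network (RBN)
   experiment and Jensen-gap convexity detectors,
4. **Ascendancy** (average mutual information) of flow networks,
5. **Spectral-exponent criticality** (1/f^β noise archetypes),
6. **Harmonic-regression spectral recovery** after disturbance.

## Fisher information of a trajectory

For a phase vector $s = (x_1,\dots,x_m)$ sampled in time, the indicator is

$$I = \frac{1}{T}\int_T \frac{s''(t)^2}{s'(t)^4}\,dt, \qquad
s' = \Big(\sum_i \dot x_i^2\Big)^{1/2}, \qquad
s'' = \frac{1}{s'}\sum_i \dot x_i\, \ddot x_i,$$

computed per sliding window of length $T$ (one cycle of the system; by
default the dominant periodogram period of the first variable). Regular,
low-variability dynamics give high, steady $I$; a regime shift shows up as
a drop. Conversely, a resilient system's $I$ returns to its
pre-disturbance band after a perturbation even when the state variable
itself does not — the pattern the package's disturbance generator plus
`detect_recovery()` reproduce end-to-end.

Numerical choices that matter:

* **Derivatives.** The non-uniform three-point stencil (the interpolating
  parabola through $t-\Delta t_p, t, t+\Delta t_a$, differentiated at the
  centre). It is exact for quadratics under any spacing and reduces to
  central differences for even spacing; the printed difference formulas
  this scheme replaces do not reduce correctly at spacing ratio 1, so the
  stencil is verified in tests against an independently solved parabola
  oracle instead. Endpoints are undefined and never enter a window.
* **Unit mixing.** Variables are min-max normalized to $[0,1]$ before
  differencing (disable with `normalize = FALSE`); $s'$ sums squared
  derivatives across variables and is meaningless across heterogeneous
  units otherwise.
* **Speed floor.** The integrand diverges wherever $s' \to 0$ — every
  turning point of a one-dimensional signal. Points with
  $s' < 0.1 \times \max_\text{window} s'$ are excluded and reported in
  `dropped_fraction`. The floor is deliberately per-window and relative:
  that preserves the exact $1/c^2$ scale equivariance of $I$ (asserted in
  tests) and discards only the turning-point neighbourhoods whose
  contribution is a discretization artifact. A near-zero floor (e.g.
  `eps_frac = 1e-6`) makes windowed $I$ on rough noise so heavy-tailed
  that the stability readings invert; with the 10% default the package's
  test suite verifies, on seeded AR(1) series, that doubling the noise
  scale lowers $I$ and raises its coefficient of variation. Even with the
  floor, windowed $I$ on noisy data remains strongly right-skewed —
  comparisons between windows are meaningful, absolute CVs below ~1 are
  not to be expected.
* **Integration.** Trapezoid rule on the retained window samples; windows
  advance by one sampling step by default.

`detect_recovery()` formalizes the "returns to previous values" reading:
baseline mean and sd of $I$ over a pre-disturbance interval (≥ 5 windows),
recovery at the first post-disturbance window from which $I$ stays at or
above `mean - k·sd` for `m` consecutive windows (defaults `k = 2`,
`m = 3`). All three constants are explicit arguments because no published
rule fixes them.

## Emergence, self-organization, complexity

Emergence is normalized Shannon information, $E = H/\log K \in [0,1]$,
self-organization its complement $S = 1 - E$, and complexity
$C = 4\,E\,S$, maximal at the order/variability balance point $E = 0.5$.
Normalization makes the log base irrelevant (base 2 internally), and the
declared alphabet size — not the observed support — sets the scale, since
possible-but-unseen states are information about order. For continuous
series, `permutation_entropy()` supplies $E$ from Bandt–Pompe ordinal
patterns (default order 4, delay 1; ties broken by temporal index, the
stable convention), which makes $E$ invariant under monotone transforms of
the data. Boolean trajectories use the two-symbol frequency directly.

## Antifragility

The fragility functional is $\oint = -\Delta C\,|\Delta x|$: positive
when a perturbation of magnitude $|\Delta x|$ destroys complexity
(fragile), zero within a tolerance (`1e-3` by default) when insensitive
(robust), negative when the system gains complexity (antifragile).

The RBN experiment generates Kauffman networks (K distinct random inputs
per node, truth-table bias 0.5 — ordered at $K=1$, critical at $K=2$,
chaotic at $K\ge 3$) and runs each twice from the same initial state: free,
and with $X$ random node states flipped every $O$ steps. $C$ is the mean
over nodes of the binary complexity of that node's state sequence;
$|\Delta x| = X\lfloor T/O\rfloor/(N\,T)$ is the fraction of node-time
states flipped, which lies in $[0,1]$ and is zero iff $X=0$. Flips are
applied after the synchronous update of event steps, so base and perturbed
runs differ only by the perturbation. With $N=20$, $X=1$, $O=1$, $T=200$,
100 replicates, the suite reproduces the qualitative ordering: ordered
networks are the most antifragile (mean $\oint < 0$ at $K=1$, and below
the $K=5$ mean).

Two scale-space detectors complement the complexity route:
`jensen_gap()` ($\mathbb E f(x) - f(\mathbb E x)$, nonnegative iff $f$
convex on the sample) and `scale_response()`, which evaluates
$\mathbb E_\sigma f(\sigma z)$ on one centered common-random-number draw
across increasing $\sigma$. Centering the draw makes linear payoffs
exactly scale-invariant in-sample, so they classify robust instead of
riding the residual mean of a finite sample. `homeostasis_profile()` adds
the skewness reading (right-skew in absorbing variables as an
antifragility indicator; thresholds $\pm 0.5$ on $g_1$).

## Ascendancy

For a nonnegative flow matrix $F$, joint probabilities $p(a_i,b_j) =
F_{ij}/\sum F$ give ascendancy as average mutual information
$K\sum_{ij} p(a_i,b_j)\log_2 [p(b_j|a_i)/p(b_j)]$, capacity as the joint
entropy, and overhead (redundancy, associated with resilience) as their
difference. $K$ defaults to 1 — pure bits, the information-theoretic form —
with total-system-throughput scaling available as `scale = "throughput"`.
Self-loops are allowed; cycling indices are out of scope.

## Criticality: the spectral exponent

`spectral_exponent()` estimates $\beta$ in $S(f)\sim 1/f^\beta$ as minus
the OLS slope of log power against log frequency over a Welch periodogram
(Hann window, segment length $n/8$, 50% overlap, per-segment mean
removal). The fit band drops the two lowest frequencies (leakage) and the
top eighth (Nyquist rolloff). Synthesized $1/f^\beta$ noise round-trips
within $\pm 0.15$ for $\beta \in [0,2]$; a genuine discrete random walk
reads $\approx 1.85$ rather than 2.0 because its exact spectrum
$\propto 1/\sin^2(\pi f)$ flattens relative to $f^{-2}$ towards Nyquist —
still inside the $\pm 0.2$ archetype band, and a property of the process,
not the estimator. `classify_noise()` maps estimates to
white/pink/brown at a 0.5 distance, `other` beyond.

## Spectral recovery

The seasonal baseline is the harmonic regression
$y_t = \alpha + \sum_{j=1}^{J}\gamma_j \sin(2\pi j t/f + \delta_j) +
\varepsilon_t$ (default $J = 3$; $j=1$ the annual cycle; $f$ observations
per year with $t$ in observation units, so a monthly series uses
$t = 0,1,2,\dots$ and $f = 12$). The phase-shifted sines are fitted
through the sin/cos linearization, keeping the fit closed-form OLS; it is
exact on any signal in the model span, and fitting uses the
pre-disturbance segment only. Deviation is the per-time Euclidean distance
across bands, $D_t = (\sum_i(\hat y_{it}-y_{it})^2)^{1/2}$, and the
recovery duration is the first post-disturbance time at which $D_t$ stays
below the 95th percentile of baseline deviations for 3 consecutive
observations. The quantile/persistence rule is this package's own
definition — the spectral-resilience concept is published without one —
and both knobs are arguments.

## Synthetic generators: what they emulate

`gen_seasonal_disturbance()` emulates a monthly 1 km² vegetation-index
pixel over an abrupt disturbance such as a stand-replacing wildfire: a
harmonic annual cycle (default mean 0.5, annual amplitude 0.25 with small
2nd/3rd harmonics — the shape of a temperate conifer NDVI record), an
immediate deficit of `drop` × the mean, exponential return at
`recovery_rate`, an asymptotic deficit `permanent_offset`, and Gaussian
observation noise (default sd 0.02, a typical monthly-composite
residual). The deficit fraction is
$\text{offset} + (\text{drop}-\text{offset})e^{-\text{rate}(t-t_d)}$ —
equal to `drop` at the event, tending to `permanent_offset` — applied to
the deterministic component *before* noise, so the stored generator truth
is exact. `gen_colored_noise()` synthesizes $1/f^\beta$ noise spectrally
(Gaussian spectrum shaped by $f^{-\beta/2}$, random phases), giving the
exact target slope in expectation with no burn-in. `gen_rbn()` and
`gen_flow_network()` produce the Boolean-network and flow fixtures with
analytically known properties (rank-one flows: AMI exactly 0; permutation
flows: AMI $=\log_2 n$).

What a green test does **not** establish: the generators produce
stationary noise, a single idealized disturbance and no missing data, so
passing suites say the estimators behave on the structure the theory
assumes — not that a particular real pixel or basin reproduces any
published recovery time. The two published headline numbers (Fisher
recovery after ~18 months at a burned pine-forest site; mean spectral
recovery ≈ 7.8 y, SD 5.3 y over Amazon Landsat samples) depend on
satellite archives and are covered here only qualitatively by the
end-to-end scenario: with a permanent offset the Fisher band is re-entered
while the state variable's final-year mean stays depressed.

## Degenerate inputs and tie-breaks

Gaps are an explicit mask (never sentinel values) and must be filled
before differentiation; boundary gaps cannot be linearly interpolated and
error. Constant variables error under z-scoring and under the spectral
exponent. Zero tangential speed flags the acceleration undefined; a window
losing every point to the speed floor yields an undefined (NA) Fisher
value rather than 0. Ordinal-pattern ties break by temporal index. Zero
joint flows contribute zero to AMI by the $0\log 0 = 0$ convention. The
autocorrelation characteristic time uses the biased (positive
semidefinite) estimator and interpolates the zero crossing linearly
between bracketing integer lags.

## Known limitations

* Windowed Fisher information on noisy series is right-skewed however the
  speed floor is set; treat it comparatively, not absolutely.
* The spectral exponent assumes a single power-law band; crossover spectra
  are averaged, not detected.
* The RBN result is the qualitative regime ordering; published ensemble
  sizes for the original experiment are not available to match exactly.
* The CLI's `--config` accepts flat `key=value` or JSON files, not YAML.
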