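test_that("fragility sign rule and antisymmetry hold", {
  expect_equal(fragility(-0.2, 0.5)$value, 0.10)
  expect_equal(fragility(-0.2, 0.5)$label, "fragile")
  expect_equal(fragility(0, 0.7)$label, "robust")
  f <- fragility(0.4, 0.25)
  expect_equal(f$value, -0.10)
  expect_equal(f$label, "antifragile")
  expect_error(fragility(0.1, -0.5), "nonnegative")
  set.seed(2)
  for (rep in 1:20) {
    dC <- runif(1, -1, 1); dx <- runif(1)
    expect_equal(fragility(-dC, dx)$value, -fragility(dC, dx)$value)
  }
})

test_that("classify_fragility respects the tolerance band", {
  tol <- 1e-3
  expect_equal(classify_fragility(0, tol), "robust")
  expect_equal(classify_fragility(tol, tol), "robust")
  expect_equal(classify_fragility(-tol, tol), "robust")
  expect_equal(classify_fragility(tol * 1.01, tol), "fragile")
  expect_equal(classify_fragility(-tol * 1.01, tol), "antifragile")
})

test_that("jensen_gap signs convexity correctly", {
  set.seed(10)
  z <- rnorm(1e4)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))  # exactly mean 0, var 1
  expect_equal(jensen_gap(function(x) x^2, z), 1, tolerance = 1e-9)
  expect_equal(jensen_gap(function(x) 3 * x - 2, z), 0, tolerance = 1e-12)
  expect_equal(jensen_gap(function(x) -x^2, z), -1, tolerance = 1e-9)
})

test_that("jensen_gap is nonnegative for convex payoffs (Jensen)", {
  set.seed(12)
  for (rep in 1:25) {
    a <- runif(1, 0, 3); b <- runif(1, 0, 2)
    cc <- runif(1, -2, 2); d <- runif(1, -1, 1)
    payoff <- function(x) a * x^2 + b * abs(x) + cc * x + d
    samples <- rnorm(200, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    expect_gte(jensen_gap(payoff, samples), -1e-10)
  }
})

test_that("scale_response classifies payoffs by scale monotonicity", {
  r <- scale_response(function(x) x^2, c(1, 2), n = 1e4, seed = 7)
  expect_equal(r$expectations[2] / r$expectations[1], 4, tolerance = 1e-9)
  expect_equal(r$verdict, "antifragile")

  expect_equal(scale_response(function(x) 0 * x + 3, c(1, 2), seed = 7)$verdict,
               "robust")

  r <- scale_response(function(x) -abs(x), c(1, 2), n = 2e5, seed = 7)
  expect_equal(r$verdict, "fragile")
  expect_close(r$expectations, -c(1, 2) * sqrt(2 / pi), 0.02)

  expect_error(scale_response(function(x) x, c(1)), "2 scales")
  expect_error(scale_response(function(x) x, c(2, 1)), "increasing")
})

test_that("scale_response is monotone for monotone-in-|x| payoffs", {
  set.seed(6)
  for (rep in 1:5) {
    k <- runif(1, 0.5, 3)
    r <- scale_response(function(x) abs(x)^k, c(0.5, 1, 2, 4),
                        n = 5000, seed = rep)
    expect_true(all(diff(r$expectations) > 0))
    expect_equal(r$verdict, "antifragile")
  }
})

test_that("homeostasis_profile classifies skewness", {
  set.seed(21)
  g <- homeostasis_profile(rnorm(1e4))
  expect_equal(g$class, "near-gaussian")
  expect_lt(abs(g$skewness), 0.1)
  ln <- homeostasis_profile(rlnorm(1e4))
  expect_equal(ln$class, "right-skewed")
  expect_equal(homeostasis_profile(-rlnorm(1e4))$class, "left-skewed")
})

test_that("rbn_step follows the truth tables synchronously", {
  # N = 1, self-input, identity table: fixed point
  id_net <- structure(list(N = 1L, K = 1L, inputs = matrix(1L, 1, 1),
                           tables = matrix(c(0L, 1L), 1), state = 1L),
                      class = "boolean_network")
  expect_equal(rbn_step(id_net)$state, 1L)
  expect_equal(rbn_step(rbn_step(id_net))$state, 1L)

  # negation table: period-2 oscillation
  neg_net <- id_net
  neg_net$tables <- matrix(c(1L, 0L), 1)
  s1 <- rbn_step(neg_net)
  expect_equal(s1$state, 0L)
  expect_equal(rbn_step(s1)$state, 1L)

  # determinism: same network and state give the same successor
  net <- gen_rbn(15, 3, seed = 5)
  expect_identical(rbn_step(net)$state, rbn_step(net)$state)
})

test_that("rbn_antifragility contracts hold", {
  pert0 <- perturbation_spec(0, 1, 100)
  r0 <- rbn_antifragility(10, 2, pert0, reps = 5, seed = 3)
  expect_identical(r0$mean, 0)
  expect_identical(r0$values, rep(0, 5))

  pert <- perturbation_spec(1, 1, 100)
  a <- rbn_antifragility(10, 2, pert, reps = 5, seed = 11)
  b <- rbn_antifragility(10, 2, pert, reps = 5, seed = 11)
  expect_identical(a$mean, b$mean)
  expect_true(all(a$values >= -1 & a$values <= 1))
  expect_error(rbn_antifragility(10, 2, perturbation_spec(11, 1, 100),
                                 reps = 2), "exceed")

  # ordered regime scores antifragile even at modest replicate counts
  ord <- rbn_antifragility(20, 1, perturbation_spec(1, 1, 200),
                           reps = 20, seed = 7)
  expect_lt(ord$mean, 0)
  expect_equal(ord$label, "antifragile")
})

test_that("perturbation_spec validates its fields", {
  expect_error(perturbation_spec(-1, 1, 10), "nonnegative")
  expect_error(perturbation_spec(1, 0, 10), "O must")
  expect_error(perturbation_spec(1, 11, 10), "O must")
})
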