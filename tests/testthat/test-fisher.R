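test_that("phase_derivatives is exact for quadratics and linears", {
  # uniform spacing, x = t^2: both derivatives exact at the interior point
  d <- phase_derivatives(eco_ts(0:2, (0:2)^2))
  expect_equal(unname(d$d1[2, 1]), 2)
  expect_equal(unname(d$d2[2, 1]), 2)
  expect_equal(d$alpha[2], 1)

  # linear signal, arbitrary uneven spacing
  tt <- c(0, 0.3, 1.1, 2.4, 2.5, 4)
  d <- phase_derivatives(eco_ts(tt, 3 * tt))
  expect_close(d$d1[2:5, 1], rep(3, 4), 1e-12)
  expect_close(d$d2[2:5, 1], rep(0, 4), 1e-10)

  # uneven spacing, x = t^2 at t = (0, 1, 3): parabola oracle says 2 and 2
  d <- phase_derivatives(eco_ts(c(0, 1, 3), c(0, 1, 9)))
  expect_equal(unname(d$d1[2, 1]), 2)
  expect_equal(unname(d$d2[2, 1]), 2)
  expect_equal(d$alpha[2], 1 / 2)

  # endpoints flagged undefined
  expect_true(all(is.na(d$d1[c(1, 3), 1])))
  expect_error(phase_derivatives(eco_ts(0:2, c(1, NA, 3))), "gaps")
})

test_that("tangential speed and acceleration match closed forms", {
  # 2-D unit circle at 1000 points per cycle: unit speed, zero acceleration
  tt <- seq(0, 6 * pi, length.out = 3001)
  d <- phase_derivatives(eco_ts(tt, cbind(cos(tt), sin(tt))))
  sp <- tangential_speed(d)
  sa <- tangential_acceleration(d)
  interior <- 2:3000
  expect_close(sp[interior], 1, 1e-4)
  expect_close(sa[interior], 0, 1e-3)

  # 1-D x = 5t
  d <- phase_derivatives(eco_ts(0:10, 5 * (0:10)))
  expect_close(tangential_speed(d)[2:10], 5, 1e-12)
  expect_close(tangential_acceleration(d)[2:10], 0, 1e-12)

  # x = t^2: s' = 2t, s'' = 2 for t > 0
  tt <- seq(1, 5, by = 0.5)
  d <- phase_derivatives(eco_ts(tt, tt^2))
  i <- 2:(length(tt) - 1)
  expect_close(tangential_speed(d)[i], 2 * tt[i], 1e-10)
  expect_close(tangential_acceleration(d)[i], 2, 1e-10)

  # stationary point: zero speed, acceleration flagged undefined
  d <- phase_derivatives(eco_ts(0:4, rep(1, 5)))
  expect_equal(tangential_speed(d)[2:4], rep(0, 3))
  expect_true(all(is.na(tangential_acceleration(d)[2:4])))
})

test_that("fisher_information vanishes on constant-speed trajectories", {
  tt <- seq(0, 8 * pi, length.out = 4001)     # 1000 points per cycle
  circ <- eco_ts(tt, cbind(cos(tt), sin(tt)))
  fs <- fisher_information(circ, window_length = 2 * pi, normalize = FALSE)
  expect_true(all(fs$fi[is.finite(fs$fi)] < 1e-6))

  lin <- eco_ts(0:199, 3.2 * (0:199))
  fs <- fisher_information(lin, window_length = 12, normalize = FALSE)
  expect_true(all(fs$fi[is.finite(fs$fi)] < 1e-20))
  expect_true(all(diff(fs$centers) > 0))
  expect_equal(length(fs$centers), length(fs$fi))
})

test_that("windowed fi equals the brute-force oracle to 1e-12", {
  set.seed(9)
  for (m in c(1L, 3L)) {
    n <- 50
    tt <- cumsum(runif(n, 0.5, 1.5))   # uneven but bounded-away-from-0 gaps
    # drifts keep s' bounded away from 0 so the 1/s'^4 integrand stays
    # well-conditioned and the two independent codes can agree to 1e-12
    vals <- sapply(seq_len(m), function(j)
      sin(tt / (1 + j)) + 0.3 * cos(0.7 * tt + j) + 1.5 * j * tt)
    ts <- eco_ts(tt, vals)
    T_win <- 10; step <- 1; eps <- 1e-9
    fs <- fisher_information(ts, T_win, step, eps_speed = eps,
                             normalize = FALSE)
    orc <- fisher_oracle(tt, vals, T_win, step, eps)
    expect_equal(fs$centers, orc$centers, tolerance = 1e-12)
    expect_close(fs$fi, orc$fi, 1e-12 * (1 + abs(orc$fi)))
  }
})

test_that("fi is shift-invariant and scales as 1/c^2", {
  set.seed(4)
  for (rep in 1:5) {
    tt <- seq(0, 30, by = 0.25)
    vals <- cbind(sin(tt) + 0.2 * sin(3.1 * tt + rep),
                  cos(0.8 * tt) + 0.1 * tt)
    ts <- eco_ts(tt, vals)
    fs <- fisher_information(ts, 8, 2, normalize = FALSE)
    shifted <- fisher_information(eco_ts(tt, vals + 5.5), 8, 2,
                                  normalize = FALSE)
    expect_close(shifted$fi, fs$fi, 1e-9 * (1 + fs$fi))
    c_ <- 3
    scaled <- fisher_information(eco_ts(tt, c_ * vals), 8, 2,
                                 normalize = FALSE)
    expect_close(scaled$fi, fs$fi / c_^2, 1e-9 * (1 + fs$fi))
  }
})

test_that("stability hypothesis: variance shift raises CV and lowers fi", {
  x_stat <- sim_ar1(600, seed = 42)
  x_shift <- sim_ar1(600, sigma = c(rep(1, 300), rep(2, 300)), seed = 42)
  fs1 <- fisher_information(eco_ts(0:599, x_stat), 12, 1)
  fs2 <- fisher_information(eco_ts(0:599, x_shift), 12, 1)
  cv <- function(v) sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  expect_lt(cv(fs1$fi), cv(fs2$fi))
  # higher variability after the shift -> lower Fisher information
  pre <- mean(fs2$fi[fs2$centers < 290], na.rm = TRUE)
  post <- mean(fs2$fi[fs2$centers > 310], na.rm = TRUE)
  expect_lt(post, pre)
})

test_that("detect_recovery finds the constructed re-entry window", {
  centers <- 1:30
  fi <- c(rep(c(0.95, 1.05), length.out = 9),   # baseline around 1, sd ~ 0.05
          rep(0.2, 6),                          # collapse at t = 10..15
          rep(1.0, 15))                         # re-entry at t = 16, stays
  fs <- make_fisher_series(centers, fi)
  expect_equal(detect_recovery(fs, baseline = c(1, 9), disturbance_time = 9.5,
                               k = 2, m = 3), 16)

  never <- make_fisher_series(centers, c(rep(c(0.95, 1.05), length.out = 9),
                                         rep(0.2, 21)))
  expect_true(is.na(detect_recovery(never, c(1, 9), 9.5, k = 2, m = 3)))

  expect_error(detect_recovery(fs, baseline = c(1, 12), disturbance_time = 9.5),
               "precede")
  expect_error(detect_recovery(fs, baseline = c(1, 3), disturbance_time = 9.5),
               "baseline too short")
})
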