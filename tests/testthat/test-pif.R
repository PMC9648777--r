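test_that("PIF vanishes for identical distributions and flat risk", {
  p <- exposure_distribution(27, 4)
  rr <- risk_function(1.3)
  expect_identical(compute_pif(rr, p, p), 0)
  # RR constant at 1: no shift can change risk (wide bounds)
  rr1 <- risk_function(1)
  ps <- shift_exposure(p, -1)
  expect_lt(abs(compute_pif(rr1, p, ps, bounds = c(1, 120))), 1e-8)
})

test_that("PIF matches the closed form for log-linear risk over a normal exposure", {
  # with the TMREL far below the support, RR(x) = rr^((x - tmrel)/5) is a
  # pure exponential and PIF = 1 - rr^(delta/5) analytically
  p <- exposure_distribution(30, 2, "normal")
  delta <- -0.5
  for (rr5 in c(1.1, 1.3, 1.8)) {
    rr <- risk_function(rr5, tmrel = 0)
    got <- compute_pif(rr, p, shift_exposure(p, delta), bounds = c(5, 60))
    expect_equal(got, 1 - rr5^(delta / 5), tolerance = 1e-6)
  }
})

test_that("PIF formula reproduces the discrete two-point analogue", {
  # half the population at RR 1, half at RR 2, moved entirely to RR 1:
  # PIF = (1.5 - 1)/1.5 = 1/3; narrow spikes emulate the point masses
  rr <- risk_function(2, tmrel = 22.5, per = 5)
  # integrate each narrow spike over its own support (adaptive rules skip
  # spikes they cannot see inside a wide interval)
  spike_num <- function(mu) {
    integrate(function(x) rr_eval(rr, x) * dnorm(x, mu, 0.01),
              mu - 0.15, mu + 0.15)$value
  }
  num <- 0.5 * spike_num(20) + 0.5 * spike_num(27.5)
  num_s <- spike_num(20)
  expect_equal((num - num_s) / num, 1 / 3, tolerance = 1e-3)
})

test_that("adaptive quadrature agrees with a fine Riemann oracle", {
  set.seed(2)
  for (k in 1:20) {
    p <- exposure_distribution(runif(1, 24, 32), runif(1, 3, 6),
                               sample(c("lognormal", "normal"), 1))
    ps <- shift_exposure(p, runif(1, -1, 0))
    rr <- risk_function(runif(1, 1.05, 2))
    bounds <- q_exposure(c(0.001, 0.999), p)
    expect_equal(compute_pif(rr, p, ps, bounds),
                 riemann_pif(rr, p, ps, bounds), tolerance = 1e-6)
  }
})

test_that("downward shifts with nondecreasing risk give nonnegative PIF", {
  set.seed(3)
  for (k in 1:25) {
    p <- exposure_distribution(runif(1, 23, 33), runif(1, 2.5, 6))
    ps <- shift_exposure(p, -runif(1, 0, 2))
    rr <- risk_function(runif(1, 1, 2.5))
    pif <- compute_pif(rr, p, ps)
    expect_gte(pif, 0)
    expect_lte(pif, 1)
  }
})

test_that("the vectorised grid PIF matches the adaptive path", {
  set.seed(4)
  means <- runif(8, 24, 32); sds <- runif(8, 3, 6); deltas <- runif(8, -1, 0)
  rrs <- c(1.15, 1.4, 1.9)
  for (j in seq_along(means)) {
    p <- exposure_distribution(means[j], sds[j])
    ps <- shift_exposure(p, deltas[j])
    bounds <- q_exposure(c(1e-5, 1 - 1e-5), p)
    pm <- ssbmslt:::.pif_grid(rrs, 22.5, 5, means[j], sds[j], deltas[j],
                              family = "lognormal",
                              lo = bounds[1], hi = bounds[2])
    for (d in seq_along(rrs)) {
      ref <- compute_pif(risk_function(rrs[d]), p, ps, bounds = bounds)
      expect_equal(pm[d, 1], ref, tolerance = 1e-6)
    }
  }
})

test_that("risk functions respect their floor and monotonicity", {
  rr <- risk_function(1.5, tmrel = 22.5)
  x <- seq(15, 45, by = 0.5)
  v <- rr_eval(rr, x)
  expect_true(all(v >= 1))
  expect_true(all(diff(v) >= 0))
  expect_equal(rr_eval(rr, 27.5), 1.5)
  expect_error(risk_function(0.9), "rr")
})
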