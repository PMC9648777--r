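test_that("one-cycle solution matches closed forms", {
  s0 <- c(S = 1, C = 0, D_dis = 0, D_other = 0)
  # nothing happens without hazards
  expect_equal(step_disease(s0, c(i = 0, r = 0, f = 0, m = 0)), s0)
  # no inflow: C and D_dis stay zero
  st <- step_disease(s0, c(i = 0, r = 0.1, f = 0.3, m = 0.02))
  expect_equal(unname(st[["C"]]), 0)
  expect_equal(unname(st[["D_dis"]]), 0)
  expect_equal(st[["S"]], exp(-0.02))
  # pure incidence: C = 1 - exp(-i)
  st2 <- step_disease(s0, c(i = 0.1, r = 0, f = 0, m = 0))
  expect_equal(st2[["C"]], 1 - exp(-0.1), tolerance = 1e-12)
  # repeated-eigenvalue case (i = r = 0, equal outflows) is handled
  st3 <- step_disease(c(S = 0.6, C = 0.4, D_dis = 0, D_other = 0),
                      c(i = 0, r = 0, f = 0, m = 0.05))
  expect_equal(st3[["S"]], 0.6 * exp(-0.05), tolerance = 1e-10)
  expect_equal(sum(st3), 1, tolerance = 1e-12)
})

test_that("annual cycle equals the matrix exponential of the intensity matrix", {
  skip_if_not_installed("Matrix")
  set.seed(6)
  for (k in 1:30) {
    hz <- c(i = runif(1, 0, 0.3), r = runif(1, 0, 0.2),
            f = runif(1, 0, 0.3), m = runif(1, 0, 0.5))
    st <- c(S = 0.7, C = 0.2, D_dis = 0.06, D_other = 0.04)
    got <- step_disease(st, hz)
    Q <- intensity_matrix(hz["i"], hz["r"], hz["f"], hz["m"])
    ref <- as.numeric(Matrix::expm(Matrix::Matrix(Q)) %*% st)
    expect_equal(unname(got), ref, tolerance = 1e-10)
  }
})

test_that("annual cycle matches a fine forward-Euler oracle", {
  set.seed(7)
  worst <- 0
  for (k in 1:30) {
    hz <- c(i = runif(1, 0, 0.3), r = runif(1, 0, 0.2),
            f = runif(1, 0, 0.3), m = runif(1, 0, 0.5))
    st <- c(S = 0.8, C = 0.15, D_dis = 0.03, D_other = 0.02)
    got <- step_disease(st, hz)
    ref <- euler_step(st, hz["i"], hz["r"], hz["f"], hz["m"])
    worst <- max(worst, max(abs(got - ref)))
  }
  expect_lt(worst, 1e-3)  # Euler at dt = 1/1024 carries O(dt) error itself
})

test_that("mass is conserved and occupancies stay nonnegative", {
  set.seed(8)
  for (k in 1:50) {
    st <- abs(rnorm(4)); st <- st / sum(st)
    names(st) <- c("S", "C", "D_dis", "D_other")
    hz <- c(i = runif(1, 0, 1), r = runif(1, 0, 1),
            f = runif(1, 0, 1), m = runif(1, 0, 1))
    out <- step_disease(st, hz)
    expect_equal(sum(out), 1, tolerance = 1e-10)
    expect_true(all(out >= 0))
  }
  expect_error(step_disease(c(S = 1, C = 0, D_dis = 0, D_other = 0),
                            c(i = -0.1, r = 0, f = 0, m = 0)), "negative")
})

test_that("incidence adjustment multiplies pathways", {
  expect_equal(adjust_incidence(0.010, 0), 0.010)
  expect_equal(adjust_incidence(0.010, 0.2), 0.008)
  expect_equal(adjust_incidence(1, 0.1, 0.1), 0.81)
  expect_error(adjust_incidence(0.01, 1.2), "pif")
  expect_error(adjust_incidence(-0.01, 0), "negative")
})

test_that("a cohort disease run composes annual cycles correctly", {
  cohort <- data.frame(age = 60:69, population = 1000,
                       all_cause_mortality = 0.015)
  stream <- data.frame(age = 60:69, incidence = 0.02, remission = 0,
                       case_fatality = 0.05)
  out <- run_disease(list(disability_weight = 0.2, annual_cost_per_case = 100),
                     stream, cohort)
  # composition oracle: fold step_disease ten times by hand
  st <- c(S = 1, C = 0, D_dis = 0, D_other = 0)
  prev_hand <- numeric(10)
  for (k in 1:10) {
    prev_hand[k] <- st[["C"]] / (st[["S"]] + st[["C"]])
    st <- step_disease(st, c(i = 0.02, r = 0, f = 0.05, m = 0.015))
  }
  expect_equal(out$prevalence, prev_hand, tolerance = 1e-12)
  expect_equal(out$m_dis, 0.05 * prev_hand, tolerance = 1e-12)
  expect_equal(out$w_dis, 0.2 * prev_hand, tolerance = 1e-12)

  # zero incidence: nothing ever happens
  stream0 <- transform(stream, incidence = 0)
  out0 <- run_disease(list(disability_weight = 0.2, annual_cost_per_case = 100),
                      stream0, cohort)
  expect_true(all(out0$prevalence == 0))
  expect_true(all(out0$cost == 0))

  # uniformly lower incidence gives uniformly lower prevalence
  stream_lo <- transform(stream, incidence = 0.015)
  out_lo <- run_disease(list(disability_weight = 0.2, annual_cost_per_case = 100),
                        stream_lo, cohort)
  expect_true(all(out_lo$prevalence[-1] < out$prevalence[-1]))
  expect_error(run_disease(list(disability_weight = 0.2, annual_cost_per_case = 1),
                           stream[1:5, ], cohort), "cover")
})
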