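test_that("the life table reproduces closed-form exponential survival", {
  ages <- 20:100
  lt <- build_life_table(ages, 1000, m_minus = rep(0.01, 81),
                         w_minus = rep(0, 81))
  expect_equal(lt$q, rep(1 - exp(-0.01), 81), tolerance = 1e-12)
  expect_equal(lt$l, 1000 * exp(-0.01)^(0:80) * 1, tolerance = 1e-9)
  # with w = 0, health-adjusted equals total person-years everywhere
  expect_equal(lt$Lw, lt$L)
  expect_equal(lt$dale, lt$e)
  # entry life expectancy near 1/m (truncation at 100 offset by the
  # exponential terminal correction)
  expect_equal(lt$e[1], 1 / 0.01, tolerance = 0.01)
})

test_that("proportional decomposition closes exactly in the comparator arm", {
  b <- get_small_bundle()
  pop <- b$population[b$population$sex == "female", ]
  pop <- pop[order(pop$age), ]
  m_all <- pop$all_cause_mortality
  set.seed(9)
  md <- runif(81, 0, 0.2) * m_all      # synthetic modelled-disease share
  lt <- build_life_table(pop$age, 100, m_minus = m_all - md,
                         w_minus = pop$pyld_rate, m_dis = md)
  expect_equal(lt$m, m_all, tolerance = 1e-12)
})

test_that("negative residual mortality aborts naming the offending age", {
  expect_error(build_life_table(60:62, 10, m_minus = c(0.01, -0.02, 0.01),
                                w_minus = rep(0, 3)),
               "age 61")
  expect_error(build_life_table(60:62, 10, m_minus = rep(0.01, 3),
                                w_minus = c(0, 0, -0.1)),
               "age 62")
})

test_that("the actuarial q convention is available and close to exponential", {
  lt1 <- build_life_table(50:60, 1, rep(0.02, 11), rep(0, 11))
  lt2 <- build_life_table(50:60, 1, rep(0.02, 11), rep(0, 11),
                          qx_convention = "actuarial")
  expect_equal(lt2$q, rep(0.02 / 1.01, 11))
  expect_equal(lt1$q, lt2$q, tolerance = 1e-4)
})

test_that("DALYs averted are zero for identical arms and positive for improvements", {
  ages <- 50:100
  n <- length(ages)
  m <- 0.005 * exp(0.07 * (ages - 50))
  lt <- build_life_table(ages, 1000, m, rep(0.1, n), m_dis = 0.003,
                         w_dis = 0.02)
  expect_equal(dalys_averted(lt, lt), rep(0, n))
  lt_int <- build_life_table(ages, 1000, m, rep(0.1, n), m_dis = 0.0015,
                             w_dis = 0.01)
  da <- dalys_averted(lt, lt_int)
  expect_true(all(da >= 0))
  expect_gt(sum(da), 0)
  expect_error(dalys_averted(list(lt), list(lt, lt)), "strata")
})

test_that("QALY accounting combines utilities and survivorship", {
  # flat utilities of 1: QALYs equal person-years
  prev <- cbind(p_normal = 0.5, p_overweight = 0.3, p_obese = 0.2)
  expect_equal(qalys_from_prevalence(1234, prev, c(1, 1, 1)), 1234)
  # worked example: 0.01 prevalence moving from obese to normal
  pre <- cbind(p_normal = 0.40, p_overweight = 0.30, p_obese = 0.30)
  post <- cbind(p_normal = 0.41, p_overweight = 0.30, p_obese = 0.29)
  u <- c(0.90, 0.85, 0.80)
  gain <- qalys_gained(qalys_from_prevalence(1000, pre, u),
                       qalys_from_prevalence(1000, post, u))
  expect_equal(gain, 1000 * 0.01 * (0.90 - 0.80))
  # equal prevalences and survival: zero gain
  expect_equal(qalys_gained(qalys_from_prevalence(500, pre, u),
                            qalys_from_prevalence(500, pre, u)), 0)
})

test_that("life-table DALYs match a large two-arm cohort microsimulation", {
  skip_if_not_installed("Matrix")
  # single-disease toy: constant hazards, cohort entering at 60
  ages <- 60:100
  n <- length(ages)
  i_comp <- 0.02; i_int <- 0.016; f <- 0.02; m_other <- 0.02
  dw <- 0.2; w_minus <- 0.05

  prev_of <- function(i) {
    st <- c(S = 1, C = 0, D_dis = 0, D_other = 0)
    pr <- numeric(n)
    for (k in seq_len(n)) {
      pr[k] <- st[["C"]] / (st[["S"]] + st[["C"]])
      st <- step_disease(st, c(i = i, r = 0, f = f, m = m_other))
    }
    pr
  }
  p_comp <- prev_of(i_comp)
  p_int <- prev_of(i_int)
  lt_comp <- build_life_table(ages, 1, rep(m_other, n), rep(w_minus, n),
                              m_dis = f * p_comp, w_dis = dw * p_comp)
  lt_int <- build_life_table(ages, 1, rep(m_other, n), rep(w_minus, n),
                             m_dis = f * p_int, w_dis = dw * p_int)
  mslt_est <- sum(dalys_averted(lt_comp, lt_int))

  # agent-based oracle: multinomial transitions under independently computed
  # annual transition matrices, identical accounting convention
  trans <- function(i) {
    # rows = source state, columns = destination (transpose of the
    # generator's action on an occupancy column)
    Q <- intensity_matrix(i, 0, f, m_other)
    t(as.matrix(Matrix::expm(Matrix::Matrix(Q))))
  }
  sim_arm <- function(P, n_agents) {
    cnt <- c(n_agents, 0, 0, 0)
    lw <- 0
    for (k in seq_len(n - 1)) {
      alive0 <- cnt[1] + cnt[2]
      if (alive0 == 0) break
      p_start <- cnt[2] / alive0
      nxt <- numeric(4)
      for (s in 1:2) if (cnt[s] > 0) {
        nxt <- nxt + as.numeric(rmultinom(1, cnt[s], P[s, ]))
      }
      nxt[3] <- nxt[3] + cnt[3]; nxt[4] <- nxt[4] + cnt[4]
      L <- (alive0 + nxt[1] + nxt[2]) / 2
      lw <- lw + L * (1 - w_minus - p_start * dw)
      cnt <- nxt
    }
    alive0 <- cnt[1] + cnt[2]
    if (alive0 > 0) {
      p_start <- cnt[2] / alive0
      m_term <- m_other + f * p_start
      lw <- lw + alive0 / m_term * (1 - w_minus - p_start * dw)
    }
    lw
  }
  set.seed(2024)
  n_batch <- 20L; agents <- 50000L
  Pc <- trans(i_comp); Pi <- trans(i_int)
  diffs <- vapply(seq_len(n_batch), function(b) {
    (sim_arm(Pi, agents) - sim_arm(Pc, agents)) / agents
  }, numeric(1))
  msim_est <- mean(diffs)
  msim_se <- sd(diffs) / sqrt(n_batch)
  expect_gt(mslt_est, 0)
  expect_lt(abs(mslt_est - msim_est), 3 * msim_se)
})
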