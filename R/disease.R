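#' @name disease_model
#' @title Four-state chronic-disease cohort model
#'
#' @description
#' Each modelled disease evolves as a continuous-time Markov process over the
#' states healthy (S), diseased (C), dead from the disease (D_dis) and dead
#' from all other causes (D_other), with constant hazards within each annual
#' cycle: incidence \eqn{i} (S to C), remission \eqn{r} (C to S), case
#' fatality \eqn{f} (C to D_dis) and other-cause mortality \eqn{m} (S and C
#' to D_other). The annual cycle is solved exactly via the matrix exponential
#' of the intensity matrix: the live 2x2 block is diagonalised in closed form
#' (both eigenvalues are real because \eqn{ir \ge 0}) and deaths accumulate
#' as hazard-weighted integrals of the live occupancies, so probability mass
#' is conserved to machine precision and competing risks cannot leak.
NULL

# Closed-form one-cycle solution of the live (S, C) block plus death inflows.
# All hazard arguments are vectorised; returns S1, C1 and the increments to
# the two death states over [0, dt].
.dz_kernel <- function(S0, C0, i, r, f, m, dt = 1) {
  n <- max(length(S0), length(C0), length(i), length(r), length(f), length(m))
  S0 <- rep_len(S0, n); C0 <- rep_len(C0, n)
  i <- rep_len(i, n); r <- rep_len(r, n)
  f <- rep_len(f, n); m <- rep_len(m, n)

  a <- i + m            # total outflow hazard from S
  b <- r + f + m        # total outflow hazard from C
  disc <- sqrt((a - b)^2 + 4 * i * r)
  lam1 <- (-(a + b) + disc) / 2
  lam2 <- (-(a + b) - disc) / 2

  # phi(lambda) = int_0^dt exp(lambda u) du, stable near lambda = 0
  phi <- function(lam) {
    out <- rep(dt, length(lam))
    nz <- abs(lam) > 1e-300
    out[nz] <- expm1(lam[nz] * dt) / lam[nz]
    out
  }

  S1 <- C1 <- IS <- IC <- numeric(n)
  deg <- disc <= 1e-10 * (a + b + 1)   # confluent (repeated eigenvalue) branch

  if (any(!deg)) {
    k <- !deg
    # spectral projections applied to the initial state
    u1S <- ((-a[k] - lam2[k]) * S0[k] + r[k] * C0[k]) / disc[k]
    u1C <- (i[k] * S0[k] + (-b[k] - lam2[k]) * C0[k]) / disc[k]
    u2S <- S0[k] - u1S
    u2C <- C0[k] - u1C
    e1 <- exp(lam1[k] * dt); e2 <- exp(lam2[k] * dt)
    p1 <- phi(lam1[k]);      p2 <- phi(lam2[k])
    S1[k] <- u1S * e1 + u2S * e2
    C1[k] <- u1C * e1 + u2C * e2
    IS[k] <- u1S * p1 + u2S * p2
    IC[k] <- u1C * p1 + u2C * p2
  }
  if (any(deg)) {
    k <- deg
    lam <- -(a[k] + b[k]) / 2
    vS <- (-a[k] - lam) * S0[k] + r[k] * C0[k]
    vC <- i[k] * S0[k] + (-b[k] - lam) * C0[k]
    el <- exp(lam * dt)
    pl <- phi(lam)
    # psi(lambda) = int_0^dt u exp(lambda u) du
    psi <- ifelse(abs(lam) > 1e-12, (dt * el - pl) / lam, dt^2 / 2)
    S1[k] <- el * (S0[k] + dt * vS)
    C1[k] <- el * (C0[k] + dt * vC)
    IS[k] <- S0[k] * pl + vS * psi
    IC[k] <- C0[k] * pl + vC * psi
  }

  list(S = pmax(S1, 0), C = pmax(C1, 0),
       d_dis = f * IC, d_other = m * (IS + IC))
}

#' Advance the four-state disease model by one cycle
#'
#' @param state numeric vector with named elements `S`, `C`, `D_dis`,
#'   `D_other`, nonnegative and summing to 1.
#' @param hazards numeric vector with named elements `i` (incidence), `r`
#'   (remission), `f` (case fatality), `m` (other-cause mortality), all
#'   nonnegative per person-year.
#' @param dt cycle length in years (default 1).
#' @return state vector after `dt` years, same names, mass conserved.
#' @examples
#' s <- c(S = 1, C = 0, D_dis = 0, D_other = 0)
#' step_disease(s, c(i = 0.1, r = 0, f = 0, m = 0))
#' @export
step_disease <- function(state, hazards, dt = 1) {
  stopifnot(all(c("S", "C", "D_dis", "D_other") %in% names(state)),
            all(c("i", "r", "f", "m") %in% names(hazards)))
  if (any(hazards < 0)) stop("step_disease: negative hazards", call. = FALSE)
  if (any(state < -1e-12)) stop("step_disease: negative state occupancy", call. = FALSE)
  k <- .dz_kernel(state[["S"]], state[["C"]],
                  hazards[["i"]], hazards[["r"]], hazards[["f"]], hazards[["m"]],
                  dt = dt)
  out <- c(S = k$S, C = k$C,
           D_dis = state[["D_dis"]] + k$d_dis,
           D_other = state[["D_other"]] + k$d_other)
  if (abs(sum(out) - sum(state)) > 1e-10) {
    stop("step_disease: mass not conserved", call. = FALSE)
  }
  out
}

#' Combine potential impact fractions with a baseline incidence
#'
#' Post-intervention incidence is `baseline * (1 - pif)`; when a disease has
#' both a BMI-mediated and a direct consumption pathway the two fractions
#' combine multiplicatively: `baseline * (1 - pif_bmi) * (1 - pif_direct)`.
#'
#' @param baseline_incidence nonnegative hazard (vectorised).
#' @param pif potential impact fraction(s), each \eqn{\le 1}; pass several as
#'   `...` to combine pathways.
#' @param ... further PIFs to combine multiplicatively.
#' @return adjusted incidence hazard.
#' @export
adjust_incidence <- function(baseline_incidence, pif, ...) {
  if (any(baseline_incidence < 0)) {
    stop("adjust_incidence: negative baseline incidence", call. = FALSE)
  }
  pifs <- c(list(pif), list(...))
  fac <- 1
  for (p in pifs) {
    if (any(p > 1 + 1e-12)) stop("adjust_incidence: pif > 1", call. = FALSE)
    fac <- fac * (1 - p)
  }
  baseline_incidence * fac
}

#' Run one disease along an ageing cohort
#'
#' Iterates [step_disease()] from the cohort's entry age to age 100 and
#' reports, per attained age: prevalence among the living, the
#' disease-specific mortality hazard contributed to the life table
#' (case fatality times prevalence), the disability (pYLD) contribution
#' (prevalence times disability weight), and the annual health-care cost
#' stream (prevalent cases alive times unit cost).
#'
#' The cohort is assumed disease-free at its entry age unless `init` is
#' given; other-cause mortality is taken from the cohort's all-cause rates.
#'
#' @param spec list with elements `disability_weight`, `annual_cost_per_case`
#'   and (optionally) `name`.
#' @param incidence_stream data.frame with `age`, `incidence`, `remission`,
#'   `case_fatality` covering every cohort age.
#' @param cohort data.frame with `age`, `population`, `all_cause_mortality`
#'   for one age-sex cohort (first row = entry age).
#' @param init optional initial state vector as in [step_disease()].
#' @return data.frame with `age`, `prevalence`, `m_dis`, `w_dis`, `cost`,
#'   `alive`.
#' @export
run_disease <- function(spec, incidence_stream, cohort, init = NULL) {
  ages <- cohort$age
  if (!all(ages %in% incidence_stream$age)) {
    stop("run_disease: incidence stream does not cover all cohort ages", call. = FALSE)
  }
  hz <- incidence_stream[match(ages, incidence_stream$age), , drop = FALSE]
  state <- if (is.null(init)) c(S = 1, C = 0, D_dis = 0, D_other = 0) else init
  n <- length(ages)
  prev <- m_dis <- w_dis <- cost <- alive <- numeric(n)
  pop0 <- cohort$population[1]
  for (k in seq_len(n)) {
    live <- state[["S"]] + state[["C"]]
    prev[k] <- if (live > 0) state[["C"]] / live else 0
    m_dis[k] <- hz$case_fatality[k] * prev[k]
    w_dis[k] <- prev[k] * spec$disability_weight
    alive[k] <- pop0 * live
    cost[k] <- prev[k] * alive[k] * spec$annual_cost_per_case
    state <- step_disease(state,
                          c(i = hz$incidence[k], r = hz$remission[k],
                            f = hz$case_fatality[k],
                            m = cohort$all_cause_mortality[k]))
  }
  data.frame(age = ages, prevalence = prev, m_dis = m_dis,
             w_dis = w_dis, cost = cost, alive = alive)
}
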