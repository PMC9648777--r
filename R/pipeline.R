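#' Run one tax scenario end-to-end
#'
#' The full pipeline for one scenario against the "business as usual"
#' comparator: price change, elasticity-driven demand and energy-intake
#' change, BMI shift, potential impact fractions on incidence, four-state
#' disease models per disease and age-sex cohort, proportional multi-state
#' life tables per arm, and payer-perspective economics. The population is a
#' closed cohort of adults aged 20-100 in the base year, aged forward until
#' everyone is dead or reaches 100.
#'
#' @param bundle an `ssb_bundle` from [generate_inputs()] / [read_bundle()].
#' @param scenario a [tax_scenario()].
#' @param bmi_trend apply the secular BMI trend (identically in both arms)?
#'   `FALSE` freezes BMI means at base-year values.
#' @param direct_pathway include the direct SSB-consumption pathway for the
#'   diseases flagged as carrying one?
#' @param qx_convention passed to [build_life_table()].
#' @param use_alt_elasticity use the bundle's alternative elasticity matrix?
#' @param rho energy-balance constant override (kcal/day per kg); default
#'   from the bundle manifest.
#' @param pif_nodes Simpson nodes for the vectorised PIF quadrature.
#' @return list of class `scenario_result`; see Details.
#' @details The result carries `totals` (discounted lifetime DALYs averted,
#'   QALYs gained, health-care cost offset, tax revenue, intervention cost,
#'   net revenue, and the payer-perspective ICER), `streams` (the same
#'   quantities by model year, undiscounted), `by_sex` breakdowns, the
#'   Table-1-style `energy` block (per 10-year band: energy and BMI change),
#'   `cases_prevented` (overweight+obesity, first year), and
#'   `disease_summary` (new cases and deaths prevented over 25 years by
#'   disease).
#' @export
run_scenario <- function(bundle, scenario = tax_scenario(),
                         bmi_trend = TRUE, direct_pathway = TRUE,
                         qx_convention = "exponential",
                         use_alt_elasticity = FALSE,
                         rho = NULL, pif_nodes = 241L) {
  cfg <- bundle$manifest$config
  if (is.null(rho)) rho <- cfg$rho
  elast <- if (use_alt_elasticity) bundle$elasticity_alt else bundle$elasticity

  pc <- price_change(scenario)
  price_vec <- stats::setNames(rep(0, length(elast$categories)),
                               elast$categories)
  price_vec["ssb"] <- pc
  dd <- demand_response(price_vec, elast)

  sexes <- unique(bundle$population$sex)
  per_sex <- lapply(sexes, function(sx) {
    .simulate_sex(bundle, scenario, sx, dd, elast,
                  bmi_trend = bmi_trend, direct_pathway = direct_pathway,
                  qx_convention = qx_convention, rho = rho,
                  pif_nodes = pif_nodes)
  })
  names(per_sex) <- sexes

  rate <- scenario$discount_rate
  nt <- max(vapply(per_sex, function(s) nrow(s$streams), integer(1)))
  agg <- function(col) {
    out <- numeric(nt)
    for (s in per_sex) out[seq_len(nrow(s$streams))] <-
        out[seq_len(nrow(s$streams))] + s$streams[[col]]
    out
  }
  streams <- data.frame(year = seq_len(nt) - 1,
                        dalys_averted = agg("dalys_averted"),
                        qalys_gained = agg("qalys_gained"),
                        cost_offset = agg("cost_offset"),
                        revenue = agg("revenue"),
                        intervention_cost = agg("intervention_cost"))

  tot_sex <- lapply(per_sex, function(s) {
    st <- s$streams
    off <- discount(st$cost_offset, rate)
    ql <- discount(st$qalys_gained, rate)
    list(dalys_averted = discount(st$dalys_averted, rate),
         qalys_gained = ql, cost_offset = off,
         revenue = discount(st$revenue, rate),
         intervention_cost = discount(st$intervention_cost, rate),
         icer = if (ql != 0) -off / ql else NA_real_)
  })
  off <- discount(streams$cost_offset, rate)
  ql <- discount(streams$qalys_gained, rate)
  rev <- discount(streams$revenue, rate)
  adm <- discount(streams$intervention_cost, rate)
  ic <- if (ql != 0) icer(off, ql) else
    list(delta_cost = -off, delta_effect = ql, icer = NA_real_, dominant = FALSE)
  totals <- list(dalys_averted = discount(streams$dalys_averted, rate),
                 qalys_gained = ql, cost_offset = off,
                 revenue = rev, intervention_cost = adm,
                 net_revenue = rev - adm,
                 icer = ic$icer, dominant = ic$dominant)

  energy <- do.call(rbind, lapply(per_sex, function(s) s$energy))
  rownames(energy) <- NULL
  disease_summary <- Reduce(function(a, b) {
    a$new_cases_prevented <- a$new_cases_prevented + b$new_cases_prevented
    a$deaths_prevented <- a$deaths_prevented + b$deaths_prevented
    a
  }, lapply(per_sex, function(s) s$disease_summary))

  structure(list(scenario = scenario, price_change_pct = pc,
                 demand_change_pct = dd, streams = streams,
                 totals = totals, by_sex = tot_sex, energy = energy,
                 cases_prevented = sum(vapply(per_sex, function(s)
                   s$cases_prevented, numeric(1))),
                 cases_prevented_by_sex = vapply(per_sex, function(s)
                   s$cases_prevented, numeric(1)),
                 disease_summary = disease_summary),
            class = "scenario_result")
}

# One sex: cohorts a0 = 20..100 followed over t = 0..(100 - a0).
.simulate_sex <- function(bundle, scenario, sex, dd, elast,
                          bmi_trend, direct_pathway, qx_convention,
                          rho, pif_nodes) {
  cfg <- bundle$manifest$config
  family <- cfg$bmi_family
  tmrel <- cfg$tmrel
  base_year <- cfg$base_year
  serv_oz <- cfg$ssb_oz_per_serving

  pop <- bundle$population[bundle$population$sex == sex, ]
  pop <- pop[order(pop$age), ]
  ages <- pop$age
  nage <- length(ages)
  bmi <- bundle$bmi[bundle$bmi$sex == sex, ]
  bmi <- bmi[order(bmi$age), ]
  cons <- bundle$consumption[bundle$consumption$sex == sex, ]
  cons <- cons[order(cons$age_lo), ]
  qw <- bundle$qaly_weights[bundle$qaly_weights$sex == sex, ]
  qw <- qw[order(qw$age_lo), ]
  dis <- bundle$diseases
  nd <- nrow(dis)

  ## demand -> energy -> BMI shift per cohort (fixed at entry age for life)
  ec <- energy_change(dd, cons, elast)
  band_of <- findInterval(ages, cons$age_lo)
  delta_tei_age <- ec$delta_tei_kcal[band_of]
  dbmi_age <- energy_to_bmi(delta_tei_age, bmi$height_m, rho)

  ## hazard matrices (disease x age)
  imat <- .hazard_matrix(bundle$disease_hazards, sex, ages, "incidence")
  rmat <- .hazard_matrix(bundle$disease_hazards, sex, ages, "remission")
  fmat <- .hazard_matrix(bundle$disease_hazards, sex, ages, "case_fatality")
  imat <- imat[dis$disease, , drop = FALSE]
  rmat <- rmat[dis$disease, , drop = FALSE]
  fmat <- fmat[dis$disease, , drop = FALSE]
  dw <- dis$disability_weight
  cost_d <- dis$annual_cost_per_case

  ## BMI-pathway PIFs on every valid (cohort, year) stratum
  valid <- outer(seq_len(nage), seq_len(nage),
                 function(c, t) c + t - 1 <= nage)   # t index 1 = year 0
  vc <- row(valid)[valid]; vt <- col(valid)[valid]
  ai <- vc + vt - 1                                  # attained-age index
  trend_off <- if (bmi_trend) bmi$trend_slope[ai] * (vt - 1) else 0
  mean_v <- bmi$bmi_mean[ai] + trend_off
  sd_v <- bmi$bmi_sd[ai]
  delta_v <- dbmi_age[vc]
  pif_bmi <- array(0, c(nd, nage, nage))
  if (any(delta_v != 0)) {
    pm <- .pif_grid(dis$rr_per_5bmi, tmrel, 5, mean_v, sd_v, delta_v,
                    family = family, n_nodes = pif_nodes)
    pif_bmi[cbind(rep(seq_len(nd), length(vc)),
                  rep(vc, each = nd), rep(vt, each = nd))] <- as.numeric(pm)
  }

  ## direct-pathway PIFs per consumption band (time-invariant)
  pif_dir_band <- matrix(0, nd, nrow(cons))
  if (direct_pathway && any(dis$direct_pathway)) {
    comp_serv <- cons$ssb_volume_mean / serv_oz
    post_serv <- pmax(ec$post_ssb_volume / serv_oz, 0.01 * comp_serv)
    dsv <- post_serv - comp_serv
    if (any(dsv != 0)) {
      dd_idx <- which(dis$direct_pathway)
      pm <- .pif_grid(dis$rr_direct_per_serving[dd_idx], 0, 1,
                      comp_serv, 0.6 * comp_serv, dsv,
                      family = family, n_nodes = pif_nodes)
      pif_dir_band[dd_idx, ] <- pm
    }
  }
  pif_dir_coh <- pif_dir_band[, band_of, drop = FALSE]  # nd x cohorts

  ## four-state recursions (other-cause mortality divided out; it scales the
  ## live states equally so prevalence among the living is unaffected)
  prevb <- .baseline_prevalence(dis$disease, bundle$disease_hazards, sex, ages)
  prevb <- prevb[dis$disease, , drop = FALSE]
  p0 <- t(prevb)                                  # cohorts x diseases
  run_arm <- function(intervention) {
    S <- 1 - p0; C <- p0
    prev <- array(NA_real_, c(nage, nd, nage))    # cohort x disease x t
    newrate <- array(NA_real_, c(nage, nd, nage)) # incidence x S-fraction
    for (tix in seq_len(nage)) {
      act <- seq_len(nage - tix + 1)              # cohorts still under 100
      aidx <- act + tix - 1
      live <- S[act, , drop = FALSE] + C[act, , drop = FALSE]
      pr <- ifelse(live > 0, C[act, , drop = FALSE] / live, 0)
      prev[act, , tix] <- pr
      i_ct <- t(imat[, aidx, drop = FALSE])
      if (intervention) {
        i_ct <- i_ct * (1 - t(pif_bmi[, , tix])[act, , drop = FALSE])
        i_ct <- i_ct * (1 - t(pif_dir_coh)[act, , drop = FALSE])
      }
      newrate[act, , tix] <- i_ct * (1 - pr)
      st <- .dz_kernel(S[act, ], C[act, ], i_ct,
                       t(rmat[, aidx, drop = FALSE]),
                       t(fmat[, aidx, drop = FALSE]), 0)
      S[act, ] <- st$S; C[act, ] <- st$C
    }
    list(prev = prev, newrate = newrate)
  }
  comp <- run_arm(FALSE)
  int <- run_arm(TRUE)

  ## disease contributions per cohort-year
  sum_md <- function(prev) {
    out <- matrix(NA_real_, nage, nage)
    for (tix in seq_len(nage)) {
      act <- seq_len(nage - tix + 1); aidx <- act + tix - 1
      out[act, tix] <- rowSums(prev[act, , tix, drop = FALSE][, , 1] *
                                 t(fmat[, aidx, drop = FALSE]))
    }
    out
  }
  sum_wd <- function(prev) {
    out <- matrix(NA_real_, nage, nage)
    for (tix in seq_len(nage)) {
      act <- seq_len(nage - tix + 1)
      out[act, tix] <- prev[act, , tix, drop = FALSE][, , 1] %*% dw
    }
    out
  }
  md_comp <- sum_md(comp$prev); md_int <- sum_md(int$prev)
  wd_comp <- sum_wd(comp$prev); wd_int <- sum_wd(int$prev)

  ## proportional life tables per cohort and arm
  L_comp <- Lw_comp <- L_int <- Lw_int <- matrix(0, nage, nage)
  for (ci in seq_len(nage)) {
    tix <- seq_len(nage - ci + 1)
    aidx <- ci + tix - 1
    m_minus <- pmax(pop$all_cause_mortality[aidx] - md_comp[ci, tix], 0)
    w_minus <- pmax(pop$pyld_rate[aidx] - wd_comp[ci, tix], 0)
    ltc <- build_life_table(ages[aidx], pop$population[ci], m_minus, w_minus,
                            md_comp[ci, tix], wd_comp[ci, tix],
                            qx_convention = qx_convention)
    lti <- build_life_table(ages[aidx], pop$population[ci], m_minus, w_minus,
                            md_int[ci, tix], wd_int[ci, tix],
                            qx_convention = qx_convention)
    L_comp[ci, tix] <- ltc$L; Lw_comp[ci, tix] <- ltc$Lw
    L_int[ci, tix] <- lti$L; Lw_int[ci, tix] <- lti$Lw
  }

  daly_stream <- colSums(Lw_int - Lw_comp)

  ## QALYs from BMI-category prevalences and survivorship
  qband_of <- findInterval(ages, qw$age_lo)
  um <- as.matrix(qw[, c("utility_normal", "utility_overweight",
                         "utility_obese")])
  cat_prev <- function(meanm) {
    # meanm: means per valid (cohort, t); returns ubar matrix (cohort x t)
    sdm <- sd_v
    d25 <- .pcat(25, meanm, sdm, family)
    d30 <- .pcat(30, meanm, sdm, family)
    u <- um[qband_of[ai], ]
    ub <- d25 * u[, 1] + (d30 - d25) * u[, 2] + (1 - d30) * u[, 3]
    M <- matrix(0, nage, nage)
    M[cbind(vc, vt)] <- ub
    M
  }
  ub_comp <- cat_prev(mean_v)
  ub_int <- cat_prev(mean_v + delta_v)
  qaly_comp <- colSums(L_comp * ub_comp)
  qaly_int <- colSums(L_int * ub_int)
  qaly_stream <- qaly_int - qaly_comp

  ## health-care cost offset
  cost_stream <- numeric(nage)
  for (tix in seq_len(nage)) {
    act <- seq_len(nage - tix + 1)
    cc <- (comp$prev[act, , tix, drop = FALSE][, , 1] * L_comp[act, tix]) %*% cost_d
    ci2 <- (int$prev[act, , tix, drop = FALSE][, , 1] * L_int[act, tix]) %*% cost_d
    cost_stream[tix] <- sum(cc - ci2)
  }

  ## tax revenue on post-tax consumption of the living (intervention arm)
  vol_post <- ec$post_ssb_volume[band_of]
  ra <- revenue_and_admin(t(L_int), vol_post, scenario)

  ## overweight/obesity cases prevented in the first year
  pre_tri <- t(vapply(seq_len(nage), function(k) {
    m0 <- bmi$bmi_mean[k]
    c(.pcat(25, m0, bmi$bmi_sd[k], family),
      .pcat(30, m0, bmi$bmi_sd[k], family))
  }, numeric(2)))
  post_tri <- t(vapply(seq_len(nage), function(k) {
    m0 <- bmi$bmi_mean[k] + dbmi_age[k]
    c(.pcat(25, m0, bmi$bmi_sd[k], family),
      .pcat(30, m0, bmi$bmi_sd[k], family))
  }, numeric(2)))
  tri <- function(m) cbind(p_normal = m[, 1], p_overweight = m[, 2] - m[, 1],
                           p_obese = 1 - m[, 2])
  cases <- cases_prevented(tri(pre_tri), tri(post_tri), pop$population)

  ## per-disease new cases and deaths prevented over 25 years
  horizon <- min(26L, nage)
  ncp <- dp <- stats::setNames(numeric(nd), dis$disease)
  for (tix in seq_len(horizon)) {
    act <- seq_len(nage - tix + 1); aidx <- act + tix - 1
    ncp <- ncp + colSums((comp$newrate[act, , tix, drop = FALSE][, , 1] -
                            int$newrate[act, , tix, drop = FALSE][, , 1]) *
                           L_comp[act, tix])
    fm <- t(fmat[, aidx, drop = FALSE])
    dp <- dp + colSums((comp$prev[act, , tix, drop = FALSE][, , 1] * fm *
                          L_comp[act, tix]) -
                         (int$prev[act, , tix, drop = FALSE][, , 1] * fm *
                            L_int[act, tix]))
  }
  disease_summary <- data.frame(disease = dis$disease,
                                new_cases_prevented = as.numeric(ncp),
                                deaths_prevented = as.numeric(dp))

  ## Table-1-style energy/BMI block
  popw <- tapply(pop$population, band_of, sum)
  dbmi_band <- tapply(dbmi_age * pop$population, band_of, sum) / popw
  energy <- data.frame(age_group = cons$age_group, sex = sex,
                       delta_ssb_kcal = ec$delta_ssb_kcal,
                       delta_tei_kcal = ec$delta_tei_kcal,
                       delta_bmi = as.numeric(dbmi_band))

  list(streams = data.frame(year = seq_len(nage) - 1,
                            dalys_averted = daly_stream,
                            qalys_gained = qaly_stream,
                            cost_offset = cost_stream,
                            revenue = ra$revenue,
                            intervention_cost = ra$intervention_cost),
       energy = energy, cases_prevented = cases,
       disease_summary = disease_summary)
}

# category CDF helper shared by the pipeline (vectorised over mean/sd)
.pcat <- function(x, mean, sd, family) {
  if (family == "normal") return(stats::pnorm(x, mean, sd))
  s2 <- log1p((sd / mean)^2)
  stats::plnorm(x, log(mean) - s2 / 2, sqrt(s2))
}
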