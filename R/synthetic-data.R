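#' @name synthetic_data
#' @title Synthetic Canada-like model inputs
#'
#' @description
#' The pipeline is exercised entirely on fabricated, internally consistent
#' inputs that emulate the shape of the real sources an SSB-tax evaluation
#' draws on: single-year age x sex population counts, all-cause mortality
#' and pYLD rates (national life tables / burden-of-disease outputs),
#' 10-year-band consumption and energy-intake summaries (nutrition-survey
#' estimates), age-specific BMI means and dispersions with a secular trend,
#' per-disease incidence / remission / case-fatality hazards with relative
#' risks, disability weights and unit treatment costs, a food-category
#' own/cross-price elasticity matrix, and obesity-related utility weights.
#' Values are placeholders with realistic magnitudes, not estimates of the
#' real Canadian tables. Everything is deterministic given the seed, and a
#' manifest records the ground-truth parameters for recovery tests.
NULL

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.disease_names <- c(
  "diabetes_mellitus_type_2", "ischaemic_heart_disease", "ischaemic_stroke",
  "intracerebral_hemorrhage", "subarachnoid_hemorrhage",
  "hypertensive_heart_disease", "atrial_fibrillation", "breast_cancer",
  "colorectal_cancer", "uterine_cancer", "ovarian_cancer", "kidney_cancer",
  "liver_cancer", "gallbladder_cancer", "pancreatic_cancer",
  "esophageal_cancer", "gastric_cardia_cancer", "thyroid_cancer",
  "leukemia", "multiple_myeloma", "non_hodgkin_lymphoma", "gout",
  "osteoarthritis", "low_back_pain", "gallbladder_biliary_disease",
  "chronic_kidney_disease", "asthma")

#' Configuration for the synthetic input generator
#'
#' Defaults define the study conditions: a closed 2015 cohort of adults aged
#' 20--100, two sexes, 27 BMI-mediated chronic diseases of which type 2
#' diabetes and ischaemic heart disease also carry a direct SSB pathway,
#' eight food categories (SSB first) with own-price SSB elasticity -1.15,
#' population scaled by 1/1000 so a full run takes seconds.
#'
#' @param seed integer RNG seed; a fixed seed reproduces every table
#'   byte-identically.
#' @param ages integer vector of single-year ages (default 20:100).
#' @param n_diseases number of chronic diseases, >= 1 (default 27).
#' @param n_food_categories number of food categories including SSB, >= 2.
#' @param base_year first calendar year of the model.
#' @param pop_scale multiplicative scale on population counts.
#' @param bmi_family `"lognormal"` or `"normal"` stratum BMI distribution.
#' @param tmrel theoretical minimum-risk BMI, kg/m2.
#' @param rho kcal/day per kg steady-state weight change.
#' @param ssb_kcal_per_oz energy density of SSBs.
#' @param ssb_oz_per_serving ounces per serving for the direct pathway.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, ages = 20:100, n_diseases = 27L,
                             n_food_categories = 8L, base_year = 2015L,
                             pop_scale = 1e-3,
                             bmi_family = c("lognormal", "normal"),
                             tmrel = 22.5, rho = 22.5,
                             ssb_kcal_per_oz = 11.8, ssb_oz_per_serving = 8) {
  bmi_family <- match.arg(bmi_family)
  if (n_diseases < 1) stop("synthetic_config: n_diseases must be >= 1", call. = FALSE)
  if (n_food_categories < 2) {
    stop("synthetic_config: n_food_categories must be >= 2 (substitution requires a second category)",
         call. = FALSE)
  }
  if (pop_scale <= 0) stop("synthetic_config: pop_scale must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), ages = ages,
                 sexes = c("female", "male"),
                 n_diseases = as.integer(n_diseases),
                 n_food_categories = as.integer(n_food_categories),
                 base_year = as.integer(base_year), pop_scale = pop_scale,
                 bmi_family = bmi_family, tmrel = tmrel, rho = rho,
                 ssb_kcal_per_oz = ssb_kcal_per_oz,
                 ssb_oz_per_serving = ssb_oz_per_serving),
            class = "synthetic_config")
}

# ten-year consumption bands over 20..100
.age_bands_10 <- function() {
  lo <- c(seq(20, 80, by = 10), 90)
  hi <- c(seq(29, 89, by = 10), 100)
  data.frame(age_lo = lo, age_hi = hi,
             age_group = paste0(lo, "-", ifelse(hi == 100, "100", hi)))
}

# five-year bands used for grouped rate inputs before interpolation
.age_bands_5 <- function() {
  lo <- seq(20, 95, by = 5)
  hi <- lo + 4
  hi[length(hi)] <- 100
  data.frame(age_lo = lo, age_hi = hi)
}

#' Generate the full synthetic input bundle
#'
#' Builds every table the pipeline consumes. Grouped rates (all-cause
#' mortality, pYLD, disease hazards) are generated on 5-year bands and
#' interpolated to single ages with [interpolate_to_single_year()]. Disease
#' case-fatality and disability-weight scales are then calibrated once,
#' deterministically, so that summed modelled-disease mortality (pYLD) never
#' exceeds 70% of the all-cause (pYLD) input in any age-sex cell - the
#' residual-feasibility condition the proportional life table requires.
#'
#' @param config a [synthetic_config()].
#' @return list of class `ssb_bundle` with elements `population`,
#'   `consumption`, `bmi`, `diseases`, `disease_hazards`, `elasticity`,
#'   `elasticity_alt`, `qaly_weights`, `manifest`.
#' @export
generate_inputs <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, .generate_inputs_impl(config))
}

.generate_inputs_impl <- function(config) {
  ages <- config$ages
  sexes <- config$sexes
  nage <- length(ages)

  ## ---- population, mortality, pYLD ----
  b5 <- .age_bands_5()
  mid5 <- (b5$age_lo + b5$age_hi) / 2
  gomp_b <- 4e-4; gomp_g <- 0.09
  sex_mort_mult <- c(female = 0.85, male = 1.18)
  pop_rows <- list()
  pop_bands <- list()
  for (sx in sexes) {
    m_band <- gomp_b * sex_mort_mult[[sx]] * exp(gomp_g * (mid5 - 20)) *
      exp(stats::rnorm(length(mid5), 0, 0.03))
    m_band <- pmin(m_band, 1.4)
    w_band <- (0.045 + 0.11 / (1 + exp(-(mid5 - 72) / 9))) *
      (if (sx == "female") 1.05 else 1) *
      exp(stats::rnorm(length(mid5), 0, 0.03))
    m1 <- interpolate_to_single_year(cbind(b5, rate = m_band), ages)$rate
    w1 <- interpolate_to_single_year(cbind(b5, rate = w_band), ages)$rate
    m1 <- pmin(m1, 1.5); w1 <- pmin(w1, 0.95)
    surv <- exp(-(gomp_b * sex_mort_mult[[sx]] / gomp_g) *
                  (exp(gomp_g * (ages - 20)) - 1))
    pop <- 470000 * surv * exp(stats::rnorm(nage, 0, 0.02)) *
      config$pop_scale * 0.5
    pop_rows[[sx]] <- data.frame(age = ages, sex = sx, population = pop,
                                 all_cause_mortality = m1, pyld_rate = w1)
    pop_bands[[sx]] <- data.frame(b5, sex = sx, mortality = m_band,
                                  pyld = w_band)
  }
  population <- do.call(rbind, pop_rows)
  rownames(population) <- NULL

  ## ---- consumption by 10-year band ----
  b10 <- .age_bands_10()
  ssb_base <- list(
    male = c(166, 138, 101, 85, 54, 66, 86, 103),
    female = c(94, 77, 58, 53, 78, 54, 68, 76))
  tei_base <- list(
    male = c(2650, 2550, 2450, 2350, 2200, 2100, 1950, 1800),
    female = c(2050, 1980, 1900, 1850, 1750, 1650, 1550, 1450))
  cons_rows <- list()
  for (sx in sexes) {
    ssb <- ssb_base[[sx]] * exp(stats::rnorm(nrow(b10), 0, 0.03))
    tei <- tei_base[[sx]] * exp(stats::rnorm(nrow(b10), 0, 0.02))
    cons_rows[[sx]] <- data.frame(
      b10, sex = sx,
      ssb_kcal_mean = ssb, ssb_kcal_se = 0.04 * ssb,
      tei_kcal_mean = tei, tei_kcal_se = 0.015 * tei,
      ssb_volume_mean = ssb / config$ssb_kcal_per_oz)
  }
  consumption <- do.call(rbind, cons_rows)
  rownames(consumption) <- NULL

  ## ---- BMI by single-year age ----
  bmi_rows <- list()
  trend_slopes <- c(female = 0.020, male = 0.025)  # kg/m2 per calendar year
  for (sx in sexes) {
    peak <- 26.8 + 1.6 * exp(-((ages - 57) / 26)^2)
    mean_bmi <- (peak - if (sx == "female") 0.5 else 0) *
      exp(stats::rnorm(nage, 0, 0.004))
    sd_bmi <- (if (sx == "female") 4.6 else 4.2) *
      exp(stats::rnorm(nage, 0, 0.01))
    height <- (if (sx == "female") 1.625 else 1.760) -
      0.0009 * pmax(ages - 40, 0) + stats::rnorm(nage, 0, 0.002)
    bmi_rows[[sx]] <- data.frame(age = ages, sex = sx, bmi_mean = mean_bmi,
                                 bmi_sd = sd_bmi,
                                 trend_slope = trend_slopes[[sx]],
                                 height_m = height)
  }
  bmi <- do.call(rbind, bmi_rows)
  rownames(bmi) <- NULL

  ## ---- diseases ----
  nd <- config$n_diseases
  dn <- if (nd <= length(.disease_names)) .disease_names[seq_len(nd)] else
    c(.disease_names, sprintf("disease_%02d", seq_len(nd - length(.disease_names)) +
                                length(.disease_names)))
  direct <- dn %in% c("diabetes_mellitus_type_2", "ischaemic_heart_disease")
  if (!any(direct)) direct[1] <- TRUE   # at least one direct pathway disease
  diseases <- data.frame(
    disease = dn,
    bmi_mediated = TRUE,
    direct_pathway = direct,
    rr_per_5bmi = pmax(exp(stats::rnorm(nd, log(1.27), 0.12)), 1.02),
    rr_direct_per_serving = ifelse(direct,
                                   pmax(exp(stats::rnorm(nd, log(1.12), 0.03)), 1.01),
                                   1),
    disability_weight = stats::runif(nd, 0.03, 0.15),
    annual_cost_per_case = exp(stats::rnorm(nd, log(4000), 0.5)),
    remission = 0)

  i0 <- exp(stats::rnorm(nd, log(1.2e-4), 0.6))
  gi <- stats::runif(nd, 0.015, 0.045)
  f0 <- stats::runif(nd, 0.004, 0.02)
  gf <- stats::runif(nd, 0.010, 0.030)
  sex_inc_mult <- matrix(exp(stats::rnorm(nd * 2, 0, 0.15)), nd, 2,
                         dimnames = list(dn, sexes))

  hz_rows <- list()
  for (d in seq_len(nd)) {
    for (sx in sexes) {
      ib <- i0[d] * sex_inc_mult[d, sx] * exp(gi[d] * (mid5 - 20)) *
        exp(stats::rnorm(length(mid5), 0, 0.04))
      fb <- f0[d] * exp(gf[d] * (mid5 - 20)) *
        exp(stats::rnorm(length(mid5), 0, 0.04))
      i1 <- interpolate_to_single_year(cbind(b5, rate = ib), ages)$rate
      f1 <- interpolate_to_single_year(cbind(b5, rate = fb), ages)$rate
      hz_rows[[paste(d, sx)]] <- data.frame(
        disease = dn[d], age = ages, sex = sx,
        incidence = i1, remission = 0, case_fatality = f1)
    }
  }
  disease_hazards <- do.call(rbind, hz_rows)
  rownames(disease_hazards) <- NULL

  ## ---- calibrate case fatality and disability weights ----
  cal <- .calibrate_feasibility(population, diseases, disease_hazards,
                                ages, sexes)
  disease_hazards$case_fatality <- disease_hazards$case_fatality * cal$f_scale
  diseases$disability_weight <- diseases$disability_weight * cal$dw_scale

  ## ---- elasticities ----
  nc <- config$n_food_categories
  cat_names <- c("ssb", "milk", "fruit_juice", "confectionery", "bakery",
                 "fruit_veg", "meat", "other_food")
  cats <- if (nc <= length(cat_names)) cat_names[seq_len(nc)] else
    c(cat_names, sprintf("category_%02d", seq_len(nc - length(cat_names))))
  E <- matrix(stats::runif(nc * nc, -0.01, 0.01), nc, nc,
              dimnames = list(cats, cats))
  diag(E) <- stats::runif(nc, -1.2, -0.4)
  E["ssb", "ssb"] <- -1.15
  # weak substitution toward SSBs' many alternatives: each cross term is
  # small because the non-SSB diet is ~20x the SSB energy base, and the
  # aggregate substitution should offset only a few percent of the SSB drop
  E[-1, "ssb"] <- stats::runif(nc - 1, 0.0005, 0.006)
  dens <- c(11.8, 18, 16, 120, 90, 12, 50, 40)
  energy_density <- stats::setNames(
    if (nc <= 8) dens[seq_len(nc)] else c(dens, rep(40, nc - 8)), cats)
  energy_density["ssb"] <- config$ssb_kcal_per_oz
  sh <- stats::runif(nc - 1, 0.5, 1.5)
  energy_share <- stats::setNames(c(0, sh / sum(sh)), cats)
  elasticity <- list(categories = cats, values = E,
                     energy_density = energy_density,
                     energy_share = energy_share)

  E_alt <- E
  E_alt["ssb", "ssb"] <- -1.04
  # the alternative matrix lacks several categories: their substitution is zero
  drop <- cats[-1][seq_len(min(3, nc - 1))]
  E_alt[drop, "ssb"] <- 0
  elasticity_alt <- list(categories = cats, values = E_alt,
                         energy_density = energy_density,
                         energy_share = energy_share)

  ## ---- obesity-related utility weights ----
  qw_rows <- list()
  for (sx in sexes) {
    u_n <- seq(0.92, 0.80, length.out = nrow(b10)) -
      (if (sx == "male") 0.005 else 0)
    qw_rows[[sx]] <- data.frame(b10, sex = sx,
                                utility_normal = u_n,
                                utility_overweight = u_n - 0.015,
                                utility_obese = u_n - 0.045)
  }
  qaly_weights <- do.call(rbind, qw_rows)
  rownames(qaly_weights) <- NULL

  manifest <- list(
    config = unclass(config),
    ground_truth = list(
      ssb_own_elasticity = -1.15,
      ssb_own_elasticity_alt = -1.04,
      rho = config$rho, tmrel = config$tmrel,
      trend_slopes = as.list(trend_slopes),
      ssb_kcal_per_oz = config$ssb_kcal_per_oz,
      gompertz = list(b = gomp_b, g = gomp_g),
      case_fatality_scale = cal$f_scale,
      disability_weight_scale = cal$dw_scale),
    uncertainty = list(
      bmi_mean_se = 0.08,       # kg/m2, systematic shift of all strata
      log_rr_se = 0.04,         # shared shift on log relative risks
      rho_se_frac = 0.10,       # relative SE on the energy-balance constant
      ssb_intake_se_scale = 1,  # multiplier on the stratum SSB-intake SEs
      elasticity_se = 0.05))    # absolute SE on the SSB own-price elasticity

  structure(list(population = population, consumption = consumption,
                 bmi = bmi, diseases = diseases,
                 disease_hazards = disease_hazards,
                 elasticity = elasticity, elasticity_alt = elasticity_alt,
                 qaly_weights = qaly_weights, manifest = manifest),
            class = "ssb_bundle")
}

# Deterministic feasibility calibration: scale case fatality so summed
# modelled-disease mortality stays below 70% of all-cause mortality in every
# age-sex cell (iterated because prevalence depends on case fatality), and
# scale disability weights so summed disease pYLD stays below 70% of the
# all-cause pYLD rate.
.calibrate_feasibility <- function(population, diseases, hazards, ages, sexes,
                                   cap = 0.7, max_iter = 20L) {
  f_scale <- 1
  for (it in seq_len(max_iter)) {
    worst <- 0
    for (sx in sexes) {
      pop <- population[population$sex == sx, ]
      pr <- .baseline_prevalence(diseases$disease, hazards, sx, ages,
                                 f_mult = f_scale)
      fmat <- .hazard_matrix(hazards, sx, ages, "case_fatality") * f_scale
      mdis <- colSums(pr * fmat)
      worst <- max(worst, max(mdis / pop$all_cause_mortality))
    }
    if (worst <= cap) break
    f_scale <- f_scale * cap / worst * 0.97
  }
  dw_scale <- 1
  for (sx in sexes) {
    pop <- population[population$sex == sx, ]
    pr <- .baseline_prevalence(diseases$disease, hazards, sx, ages,
                               f_mult = f_scale)
    wdis <- colSums(pr * diseases$disability_weight)
    dw_scale <- min(dw_scale, cap * min(pop$pyld_rate / pmax(wdis, 1e-12)))
  }
  list(f_scale = f_scale, dw_scale = min(dw_scale, 1))
}

# (diseases x ages) matrix of one hazard column for one sex
.hazard_matrix <- function(hazards, sex, ages, col) {
  h <- hazards[hazards$sex == sex, ]
  out <- matrix(0, length(unique(h$disease)), length(ages),
                dimnames = list(unique(h$disease), ages))
  for (d in rownames(out)) {
    hd <- h[h$disease == d, ]
    out[d, ] <- hd[[col]][match(ages, hd$age)]
  }
  out
}

# Baseline prevalence-by-age for every disease of one sex: the live-block
# recursion from age 20 with other-cause mortality divided out (it scales S
# and C equally, so prevalence among the living is unaffected).
.baseline_prevalence <- function(disease_names, hazards, sex, ages,
                                 f_mult = 1, i_mult = 1) {
  imat <- .hazard_matrix(hazards, sex, ages, "incidence") * i_mult
  rmat <- .hazard_matrix(hazards, sex, ages, "remission")
  fmat <- .hazard_matrix(hazards, sex, ages, "case_fatality") * f_mult
  nd <- nrow(imat)
  S <- rep(1, nd); C <- rep(0, nd)
  prev <- matrix(0, nd, length(ages), dimnames = dimnames(imat))
  for (k in seq_along(ages)) {
    live <- S + C
    prev[, k] <- ifelse(live > 0, C / live, 0)
    st <- .dz_kernel(S, C, imat[, k], rmat[, k], fmat[, k], 0)
    S <- st$S; C <- st$C
  }
  prev
}
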