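#' Probabilistic sensitivity analysis (Monte Carlo over sampled inputs)
#'
#' Re-runs the full pipeline with jointly re-sampled inputs: the stratum BMI
#' means (normal shift, one draw shared across strata), the relative risks
#' (lognormal, a shared shift on the log scale applied to both pathways),
#' the energy-balance constant rho (normal, relative), baseline SSB intake
#' (normal on each stratum mean with its standard error, one shared z), and
#' the SSB own-price elasticity (normal). One draw per parameter family per
#' iteration, shared across strata, preserving the correlation structure of
#' a systematic parameter error. Point estimate is the mean over iterations;
#' the uncertainty interval is the empirical 2.5th/97.5th percentile.
#'
#' @param bundle an `ssb_bundle`.
#' @param scenario a [tax_scenario()].
#' @param iterations number of Monte Carlo iterations (>= 2).
#' @param seed RNG seed; a fixed seed reproduces the UI exactly.
#' @param interval_level central interval mass (default 0.95).
#' @param zero_variance if `TRUE`, all sampling SDs are set to zero
#'   (degenerate run; every iteration identical).
#' @param ... passed to [run_scenario()].
#' @return list with `summary` (outcome, mean, lower, upper), `draws`
#'   (iterations x outcomes matrix), and `n_failed`.
#' @export
run_psa <- function(bundle, scenario = tax_scenario(), iterations = 2000L,
                    seed = 1L, interval_level = 0.95,
                    zero_variance = FALSE, ...) {
  if (iterations < 2) stop("run_psa: iterations must be >= 2", call. = FALSE)
  unc <- bundle$manifest$uncertainty
  if (zero_variance) unc <- lapply(unc, function(x) 0)
  Z <- with_seed(seed, matrix(stats::rnorm(iterations * 5), iterations, 5))
  outcomes <- c("dalys_averted", "qalys_gained", "cost_offset",
                "revenue", "intervention_cost", "icer")
  draws <- matrix(NA_real_, iterations, length(outcomes),
                  dimnames = list(NULL, outcomes))
  n_failed <- 0L
  for (it in seq_len(iterations)) {
    res <- tryCatch(
      run_scenario(.perturb_bundle(bundle, Z[it, ], unc), scenario,
                   rho = bundle$manifest$config$rho *
                     max(1 + Z[it, 3] * unc$rho_se_frac, 0.05), ...),
      error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    draws[it, ] <- unlist(res$totals[outcomes])
  }
  if (n_failed > 0.01 * iterations) {
    stop("run_psa: more than 1% of iterations failed (", n_failed, ")",
         call. = FALSE)
  }
  a <- (1 - interval_level) / 2
  ok <- stats::complete.cases(draws)
  summary <- data.frame(
    outcome = outcomes,
    mean = colMeans(draws[ok, , drop = FALSE]),
    lower = apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = a),
    upper = apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = 1 - a),
    row.names = NULL)
  list(summary = summary, draws = draws, n_failed = n_failed)
}

# one Monte-Carlo perturbation of the input bundle
.perturb_bundle <- function(bundle, z, unc) {
  b <- bundle
  b$bmi$bmi_mean <- pmax(b$bmi$bmi_mean + z[1] * unc$bmi_mean_se, 15)
  fac <- exp(z[2] * unc$log_rr_se)
  b$diseases$rr_per_5bmi <- pmax(b$diseases$rr_per_5bmi ^ fac, 1)
  b$diseases$rr_direct_per_serving <-
    pmax(b$diseases$rr_direct_per_serving ^ fac, 1)
  # z[3] is used for rho by the caller
  kcal <- pmax(b$consumption$ssb_kcal_mean +
                 z[4] * unc$ssb_intake_se_scale * b$consumption$ssb_kcal_se, 1)
  kcal <- pmin(kcal, b$consumption$tei_kcal_mean)
  scale <- kcal / b$consumption$ssb_kcal_mean
  b$consumption$ssb_kcal_mean <- kcal
  b$consumption$ssb_volume_mean <- b$consumption$ssb_volume_mean * scale
  e <- b$elasticity
  e$values["ssb", "ssb"] <- min(e$values["ssb", "ssb"] +
                                  z[5] * unc$elasticity_se, -0.01)
  b$elasticity <- e
  b
}

#' Univariate sensitivity scenarios
#'
#' Deterministic (zero-variance) re-runs of the pipeline with exactly one
#' parameter family patched per scenario: freeze the secular BMI trend
#' (`static_bmi`), 80%/120% tax pass-through, a 3% discount rate, or the
#' alternative (US-style) price-elasticity matrix.
#'
#' @param bundle an `ssb_bundle`.
#' @param base a [tax_scenario()]; the base case.
#' @param scenarios character vector of scenario names.
#' @param ... passed to [run_scenario()].
#' @return data.frame: one row per scenario (plus the base), absolute
#'   outcomes and percent change vs base for DALYs averted, QALYs gained,
#'   health-care cost offset and net revenue.
#' @export
run_sensitivity <- function(bundle, base = tax_scenario(),
                            scenarios = c("static_bmi", "passthrough_80",
                                          "passthrough_120", "discount_3pct",
                                          "alt_elasticities"), ...) {
  known <- c("static_bmi", "passthrough_80", "passthrough_120",
             "discount_3pct", "alt_elasticities")
  if (!all(scenarios %in% known)) {
    stop("run_sensitivity: unknown scenario: ",
         paste(setdiff(scenarios, known), collapse = ", "), call. = FALSE)
  }
  run1 <- function(name) {
    sc <- base
    args <- list(bundle = bundle, ...)
    if (name == "passthrough_80") sc$pass_through <- 0.8
    if (name == "passthrough_120") sc$pass_through <- 1.2
    if (name == "discount_3pct") sc$discount_rate <- 0.03
    if (name == "static_bmi") args$bmi_trend <- FALSE
    if (name == "alt_elasticities") args$use_alt_elasticity <- TRUE
    args$scenario <- sc
    do.call(run_scenario, args)$totals
  }
  rows <- c(list(base = run1("base")), lapply(stats::setNames(scenarios, scenarios), run1))
  cols <- c("dalys_averted", "qalys_gained", "cost_offset", "net_revenue")
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    tt <- rows[[nm]]
    data.frame(scenario = nm,
               dalys_averted = tt$dalys_averted,
               qalys_gained = tt$qalys_gained,
               cost_offset = tt$cost_offset,
               net_revenue = tt$net_revenue)
  }))
  base_row <- out[out$scenario == "base", cols]
  for (cl in cols) {
    out[[paste0("pct_", cl)]] <- 100 * (out[[cl]] - base_row[[cl]]) /
      abs(base_row[[cl]])
  }
  out
}

#' Compare tax levels
#'
#' Runs the pipeline at several volumetric tax levels on shared inputs.
#'
#' @param bundle an `ssb_bundle`.
#' @param taxes tax levels in CAD/oz.
#' @param base a [tax_scenario()] supplying the non-tax parameters.
#' @param ... passed to [run_scenario()].
#' @return data.frame: one row per tax level with price change, DALYs
#'   averted, QALYs gained, cost offset, revenue and intervention cost.
#' @export
run_tax_ladder <- function(bundle, taxes = c(0.01, 0.015, 0.02),
                           base = tax_scenario(), ...) {
  do.call(rbind, lapply(taxes, function(tx) {
    sc <- base
    sc$tax_per_oz <- tx
    r <- run_scenario(bundle, sc, ...)
    data.frame(tax_per_oz = tx, price_change_pct = r$price_change_pct,
               dalys_averted = r$totals$dalys_averted,
               qalys_gained = r$totals$qalys_gained,
               cost_offset = r$totals$cost_offset,
               revenue = r$totals$revenue,
               intervention_cost = r$totals$intervention_cost)
  }))
}
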