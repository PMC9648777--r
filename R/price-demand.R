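#' Define a tax scenario
#'
#' A flat volumetric excise on sugar-sweetened beverages. Defaults follow the
#' base case: CAD$0.015/oz on a CAD$0.10/oz baseline price, 100%
#' pass-through, outcomes discounted at 1.5% per year.
#'
#' @param tax_per_oz tax in CAD per ounce, >= 0.
#' @param pass_through fraction of the tax appearing in the consumer price,
#'   in `[0, 2]`.
#' @param baseline_price_per_oz pre-tax SSB price, CAD/oz, > 0.
#' @param discount_rate annual discount rate for health and cost outcomes.
#' @param admin_share intervention (administration) cost as a share of tax
#'   revenue.
#' @return object of class `tax_scenario`.
#' @export
tax_scenario <- function(tax_per_oz = 0.015, pass_through = 1.0,
                         baseline_price_per_oz = 0.10,
                         discount_rate = 0.015, admin_share = 0.02) {
  if (tax_per_oz < 0) stop("tax_scenario: tax_per_oz must be >= 0", call. = FALSE)
  if (pass_through < 0 || pass_through > 2) {
    stop("tax_scenario: pass_through must be in [0, 2]", call. = FALSE)
  }
  if (baseline_price_per_oz <= 0) {
    stop("tax_scenario: baseline price must be > 0", call. = FALSE)
  }
  if (discount_rate < 0) stop("tax_scenario: discount_rate must be >= 0", call. = FALSE)
  structure(list(tax_per_oz = tax_per_oz, pass_through = pass_through,
                 baseline_price_per_oz = baseline_price_per_oz,
                 discount_rate = discount_rate, admin_share = admin_share),
            class = "tax_scenario")
}

#' Percent price change implied by a tax scenario
#'
#' `100 * tax_per_oz * pass_through / baseline_price_per_oz`; e.g. a
#' CAD$0.015/oz tax fully passed through on a CAD$0.10/oz base raises the
#' price 15%.
#'
#' @param scenario a [tax_scenario()].
#' @return percent change in the SSB price.
#' @export
price_change <- function(scenario) {
  100 * scenario$tax_per_oz * scenario$pass_through /
    scenario$baseline_price_per_oz
}

#' Demand response to category price changes
#'
#' Linear elasticity rule: the percent demand change of category i is
#' `sum_j elasticity(i, j) * price_change(j)`, i.e. the elasticity matrix
#' applied to the price-change vector. Elasticities are assumed identical
#' across age-sex strata; stratum differences in absolute consumption change
#' come from baseline consumption alone.
#'
#' @param price_changes named percent price changes by food category.
#' @param elasticity an elasticity object (list with `categories` and
#'   `values`, the percent-per-percent matrix).
#' @return named percent demand change per category.
#' @export
demand_response <- function(price_changes, elasticity) {
  cats <- elasticity$categories
  if (!setequal(names(price_changes), cats)) {
    stop("demand_response: category mismatch between prices and elasticities",
         call. = FALSE)
  }
  pc <- price_changes[cats]
  out <- as.numeric(elasticity$values %*% pc)
  names(out) <- cats
  out
}

#' Energy-intake change per age-sex stratum
#'
#' Converts percent demand changes per category into kcal/day changes per
#' stratum. The SSB change applies to the stratum's baseline SSB energy; the
#' substitution response of each other category applies to that category's
#' share of the stratum's non-SSB energy (the `energy_share` column of the
#' elasticity object). Post-tax SSB volume is floored at zero. The change is
#' a one-time shift held constant over the model horizon.
#'
#' @param demand_changes named percent demand changes from
#'   [demand_response()].
#' @param consumption baseline consumption table (rows = 10-year age band x
#'   sex; columns `ssb_kcal_mean`, `tei_kcal_mean`, `ssb_volume_mean`, ...).
#' @param elasticity elasticity object carrying `categories` and
#'   `energy_share` (share of non-SSB energy per non-SSB category).
#' @return `consumption` with added columns `delta_ssb_kcal`,
#'   `delta_tei_kcal`, `delta_ssb_volume`, `post_ssb_volume`.
#' @export
energy_change <- function(demand_changes, consumption, elasticity) {
  cats <- elasticity$categories
  if (!setequal(names(demand_changes), cats)) {
    stop("energy_change: category mismatch", call. = FALSE)
  }
  need <- c("ssb_kcal_mean", "tei_kcal_mean", "ssb_volume_mean")
  if (!all(need %in% names(consumption))) {
    stop("energy_change: consumption table missing columns: ",
         paste(setdiff(need, names(consumption)), collapse = ", "),
         call. = FALSE)
  }
  ssb <- cats[1]
  other <- cats[-1]
  d_ssb_pct <- demand_changes[[ssb]]
  # clamp so post-tax consumption cannot go negative
  d_ssb_pct <- max(d_ssb_pct, -100)
  dk_ssb <- d_ssb_pct / 100 * consumption$ssb_kcal_mean
  non_ssb_kcal <- pmax(consumption$tei_kcal_mean - consumption$ssb_kcal_mean, 0)
  shares <- elasticity$energy_share[other]
  d_other <- sum(demand_changes[other] / 100 * shares)  # per kcal of non-SSB energy
  dk_other <- d_other * non_ssb_kcal
  out <- consumption
  out$delta_ssb_kcal <- dk_ssb
  out$delta_tei_kcal <- dk_ssb + dk_other
  out$delta_ssb_volume <- d_ssb_pct / 100 * consumption$ssb_volume_mean
  out$post_ssb_volume <- pmax(consumption$ssb_volume_mean + out$delta_ssb_volume, 0)
  out
}
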