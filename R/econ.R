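#' Discount a yearly stream to its present value
#'
#' `sum_t stream(t) / (1 + rate)^t` with `t = 0` for the first model year
#' (the 2015 reference year is undiscounted).
#'
#' @param stream numeric vector by model year.
#' @param rate annual discount rate, >= 0.
#' @return discounted total (scalar).
#' @examples
#' discount(c(0, 0, 100), 0.015)  # 100 / 1.015^2 = 97.066
#' @export
discount <- function(stream, rate) {
  if (rate < 0) stop("discount: rate must be >= 0", call. = FALSE)
  t <- seq_along(stream) - 1
  sum(stream / (1 + rate)^t)
}

#' Tax revenue and intervention (administration) cost streams
#'
#' Revenue accrues on post-tax consumption by the living population:
#' `revenue(year) = sum over strata of alive person-years x oz/person/day x
#' 365.25 x tax_per_oz`. Intervention cost is a fixed administrative share of
#' revenue each year (default 2%).
#'
#' @param alive matrix of person-years alive (years x strata) or a vector.
#' @param consumption_oz post-tax SSB consumption, oz/person/day, per
#'   stratum (recycled over years; consumption is a one-time shift held
#'   constant).
#' @param scenario a [tax_scenario()].
#' @return data.frame by year: `revenue`, `intervention_cost`, `net_revenue`
#'   (CAD).
#' @export
revenue_and_admin <- function(alive, consumption_oz, scenario) {
  if (any(consumption_oz < 0)) {
    stop("revenue_and_admin: negative consumption", call. = FALSE)
  }
  alive <- cbind(alive)
  if (length(consumption_oz) != ncol(alive)) {
    stop("revenue_and_admin: consumption/strata mismatch", call. = FALSE)
  }
  revenue <- as.numeric(alive %*% consumption_oz) * 365.25 * scenario$tax_per_oz
  cost <- scenario$admin_share * revenue
  data.frame(revenue = revenue, intervention_cost = cost,
             net_revenue = revenue - cost)
}

#' Incremental cost-effectiveness ratio, payer perspective
#'
#' The health-care cost offset enters as a negative incremental cost (the
#' tax arm saves treatment costs); tax revenue and administration costs are
#' transfers excluded under the public-payer perspective:
#' `icer = -cost_offset / qalys`.
#'
#' @param cost_offset discounted health-care costs saved (CAD, positive =
#'   savings).
#' @param qalys discounted QALYs gained.
#' @return list with `delta_cost` (CAD), `delta_effect` (QALYs), `icer`
#'   (CAD/QALY, `NA` when `qalys == 0`), and `dominant` (TRUE when the
#'   intervention saves money and gains QALYs).
#' @export
icer <- function(cost_offset, qalys) {
  delta_cost <- -cost_offset
  out <- list(delta_cost = delta_cost, delta_effect = qalys,
              icer = NA_real_,
              dominant = isTRUE(delta_cost < 0 && qalys > 0))
  if (qalys == 0) {
    warning("icer: zero QALY difference; ICER undefined")
    return(out)
  }
  out$icer <- delta_cost / qalys
  out
}
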