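#' Render a human-readable summary of scenario results
#'
#' Formats the main outputs of one or more runs as plain-text tables:
#' energy/BMI change by age-sex band, lifetime outcomes by sex with the
#' ICER (annotated as dominant when the tax both saves costs and gains
#' QALYs), an optional sensitivity block (percent change vs base) and an
#' optional tax-ladder block.
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param sensitivity optional data.frame from [run_sensitivity()].
#' @param ladder optional data.frame from [run_tax_ladder()].
#' @return character vector of report lines (also printed invisibly
#'   friendly via `cat`).
#' @export
render_report <- function(result, sensitivity = NULL, ladder = NULL) {
  fm <- function(x, d = 1) formatC(x, format = "f", digits = d, big.mark = ",")
  out <- c(
    "SSB tax simulation report",
    sprintf("  tax: CAD$%.3f/oz, pass-through %.0f%%, price change %+.1f%%",
            result$scenario$tax_per_oz, 100 * result$scenario$pass_through,
            result$price_change_pct),
    sprintf("  SSB demand change: %+.2f%%", result$demand_change_pct[["ssb"]]),
    "",
    "Energy and BMI change by age group and sex:",
    sprintf("  %-9s %-7s %12s %12s %9s", "age", "sex", "dSSB kcal/d",
            "dTEI kcal/d", "dBMI"))
  e <- result$energy
  out <- c(out, sprintf("  %-9s %-7s %12s %12s %9s", e$age_group, e$sex,
                        fm(e$delta_ssb_kcal, 2), fm(e$delta_tei_kcal, 2),
                        fm(e$delta_bmi, 3)))
  out <- c(out, "",
           sprintf("Overweight/obesity cases prevented (first year): %s",
                   fm(result$cases_prevented, 0)))
  t2 <- result$totals
  dom <- if (isTRUE(t2$dominant)) "  [dominant: cost-saving and health-gaining]" else ""
  out <- c(out, "", "Lifetime outcomes (discounted):",
           sprintf("  DALYs averted:           %s", fm(t2$dalys_averted, 0)),
           sprintf("  QALYs gained:            %s", fm(t2$qalys_gained, 0)),
           sprintf("  Health-care cost offset: CAD$%s", fm(t2$cost_offset, 0)),
           sprintf("  Tax revenue:             CAD$%s", fm(t2$revenue, 0)),
           sprintf("  Intervention cost:       CAD$%s", fm(t2$intervention_cost, 0)),
           sprintf("  Net revenue:             CAD$%s", fm(t2$net_revenue, 0)),
           sprintf("  ICER (CAD$/QALY):        %s%s", fm(t2$icer, 0), dom))
  for (sx in names(result$by_sex)) {
    b <- result$by_sex[[sx]]
    out <- c(out, sprintf("  [%s] DALYs %s | QALYs %s | offset CAD$%s | ICER %s",
                          sx, fm(b$dalys_averted, 0), fm(b$qalys_gained, 0),
                          fm(b$cost_offset, 0), fm(b$icer, 0)))
  }
  if (!is.null(sensitivity)) {
    out <- c(out, "", "Sensitivity analyses (% change vs base):")
    out <- c(out, sprintf("  %-16s %10s %10s %10s %10s", "scenario",
                          "DALYs", "QALYs", "offset", "net rev"))
    s <- sensitivity[sensitivity$scenario != "base", ]
    out <- c(out, sprintf("  %-16s %9s%% %9s%% %9s%% %9s%%", s$scenario,
                          fm(s$pct_dalys_averted, 1), fm(s$pct_qalys_gained, 1),
                          fm(s$pct_cost_offset, 1), fm(s$pct_net_revenue, 1)))
  }
  if (!is.null(ladder)) {
    out <- c(out, "", "Tax ladder:")
    out <- c(out, sprintf("  %-10s %8s %12s %12s %14s", "CAD$/oz", "dPrice",
                          "DALYs", "QALYs", "revenue"))
    out <- c(out, sprintf("  %-10s %7s%% %12s %12s %14s",
                          formatC(ladder$tax_per_oz, format = "f", digits = 3),
                          fm(ladder$price_change_pct, 0),
                          fm(ladder$dalys_averted, 0),
                          fm(ladder$qalys_gained, 0), fm(ladder$revenue, 0)))
  }
  out
}
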