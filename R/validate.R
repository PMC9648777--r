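#' Validate an input bundle against its schema invariants
#'
#' Checks every declared range and consistency condition (nonnegative
#' populations and hazards, pYLD < 1, SSB energy within total energy,
#' positive standard errors, BMI and height ranges, negative SSB own-price
#' elasticity, direct-pathway flags, monotone utility ordering) and the
#' residual-feasibility pre-condition of the proportional life table:
#' summed modelled-disease mortality and pYLD must not exceed the all-cause
#' inputs in any age-sex cell. All violations are reported, not just the
#' first.
#'
#' @param bundle an `ssb_bundle`.
#' @return data.frame with columns `table`, `check`, `detail`; zero rows
#'   when the bundle is valid.
#' @export
validate_inputs <- function(bundle) {
  v <- list()
  add <- function(table, check, detail) {
    v[[length(v) + 1]] <<- data.frame(table = table, check = check,
                                      detail = detail)
  }
  p <- bundle$population
  if (any(p$population < 0)) add("population", "population >= 0",
                                 "negative population count")
  if (any(p$all_cause_mortality < 0 | p$all_cause_mortality > 1.5))
    add("population", "mortality in [0, 1.5]", "out-of-range mortality rate")
  if (any(p$pyld_rate < 0 | p$pyld_rate >= 1))
    add("population", "pyld in [0, 1)", "out-of-range pYLD rate")

  cn <- bundle$consumption
  if (any(cn$ssb_kcal_mean < 0 | cn$ssb_kcal_mean > cn$tei_kcal_mean))
    add("consumption", "0 <= ssb_kcal <= tei_kcal", "SSB energy exceeds TEI")
  if (any(cn$ssb_kcal_se <= 0 | cn$tei_kcal_se <= 0))
    add("consumption", "se > 0", "nonpositive standard error")

  bm <- bundle$bmi
  if (any(bm$bmi_mean < 15 | bm$bmi_mean > 45))
    add("bmi", "bmi_mean in [15, 45]", "out-of-range BMI mean")
  if (any(bm$bmi_sd <= 0)) add("bmi", "bmi_sd > 0", "nonpositive BMI sd")
  if (any(bm$height_m < 1.2 | bm$height_m > 2.1))
    add("bmi", "height in [1.2, 2.1]", "out-of-range height")

  ds <- bundle$diseases
  if (any(ds$rr_per_5bmi < 1)) add("diseases", "rr_per_5bmi >= 1",
                                   "relative risk below 1")
  if (any(ds$rr_direct_per_serving[!ds$direct_pathway] != 1))
    add("diseases", "direct RR only on flagged diseases",
        "non-flagged disease carries a direct RR")
  if (any(ds$disability_weight < 0 | ds$disability_weight >= 1))
    add("diseases", "disability_weight in [0, 1)", "out-of-range weight")
  if (any(ds$annual_cost_per_case < 0))
    add("diseases", "cost >= 0", "negative unit cost")

  hz <- bundle$disease_hazards
  for (cl in c("incidence", "remission", "case_fatality")) {
    if (any(hz[[cl]] < 0)) add("disease_hazards", paste(cl, ">= 0"),
                               paste("negative", cl))
  }

  el <- bundle$elasticity
  if (el$values["ssb", "ssb"] >= 0)
    add("elasticity", "SSB own-price elasticity < 0",
        "nonnegative own-price entry")
  if (any(!is.finite(el$values))) add("elasticity", "finite matrix",
                                      "non-finite elasticity")
  if (any(el$energy_density < 0)) add("elasticity", "energy_density >= 0",
                                      "negative energy density")

  qw <- bundle$qaly_weights
  if (any(qw$utility_normal < qw$utility_overweight |
            qw$utility_overweight < qw$utility_obese))
    add("qaly_weights", "u_normal >= u_overweight >= u_obese",
        "non-monotone utility ordering")
  if (any(qw$utility_obese < 0 | qw$utility_normal > 1))
    add("qaly_weights", "utilities in [0, 1]", "out-of-range utility")

  ## residual feasibility: modelled diseases must fit inside all-cause inputs
  ages <- sort(unique(p$age))
  for (sx in unique(p$sex)) {
    pv <- .baseline_prevalence(ds$disease, hz, sx, ages)
    fmat <- .hazard_matrix(hz, sx, ages, "case_fatality")
    mdis <- colSums(pv[ds$disease, , drop = FALSE] *
                      fmat[ds$disease, , drop = FALSE])
    wdis <- colSums(pv[ds$disease, , drop = FALSE] * ds$disability_weight)
    ps <- p[p$sex == sx, ]
    ps <- ps[order(ps$age), ]
    bad_m <- which(mdis > ps$all_cause_mortality)
    bad_w <- which(wdis > ps$pyld_rate)
    if (length(bad_m)) add("disease_hazards", "residual mortality >= 0",
                           paste0("summed disease mortality exceeds all-cause at ",
                                  sx, " age ", paste(ages[bad_m], collapse = ",")))
    if (length(bad_w)) add("diseases", "residual pYLD >= 0",
                           paste0("summed disease pYLD exceeds all-cause at ",
                                  sx, " age ", paste(ages[bad_w], collapse = ",")))
  }

  if (length(v) == 0) {
    return(data.frame(table = character(), check = character(),
                      detail = character()))
  }
  do.call(rbind, v)
}
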