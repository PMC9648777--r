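#' Write a synthetic input bundle to disk
#'
#' One headered UTF-8 CSV per table ('.' decimal), the elasticity matrices as
#' wide CSVs, and a JSON manifest of the ground-truth parameters. The
#' manifest gains an `md5` map over the written CSVs so regeneration under
#' the same seed can be verified checksum-for-checksum.
#'
#' @param bundle an `ssb_bundle` from [generate_inputs()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(bundle$population, "population")
  wr(bundle$consumption, "consumption")
  wr(bundle$bmi, "bmi")
  wr(bundle$diseases, "diseases")
  wr(bundle$disease_hazards, "disease_hazards")
  em <- function(el) {
    data.frame(category = el$categories,
               energy_density = el$energy_density[el$categories],
               energy_share = el$energy_share[el$categories],
               as.data.frame(el$values), check.names = FALSE)
  }
  wr(em(bundle$elasticity), "elasticity")
  wr(em(bundle$elasticity_alt), "elasticity_alt")
  wr(bundle$qaly_weights, "qaly_weights")
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- bundle$manifest
  manifest$md5 <- as.list(tools::md5sum(csvs))
  names(manifest$md5) <- basename(csvs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing the CSVs and `manifest.json`.
#' @return an `ssb_bundle`.
#' @export
read_bundle <- function(dir) {
  rd <- function(name) {
    utils::read.csv(file.path(dir, paste0(name, ".csv")),
                    check.names = FALSE, fileEncoding = "UTF-8")
  }
  re <- function(name) {
    df <- rd(name)
    cats <- df$category
    vals <- as.matrix(df[, cats, drop = FALSE])
    rownames(vals) <- cats
    list(categories = cats, values = vals,
         energy_density = stats::setNames(df$energy_density, cats),
         energy_share = stats::setNames(df$energy_share, cats))
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(population = rd("population"), consumption = rd("consumption"),
                 bmi = rd("bmi"), diseases = rd("diseases"),
                 disease_hazards = rd("disease_hazards"),
                 elasticity = re("elasticity"),
                 elasticity_alt = re("elasticity_alt"),
                 qaly_weights = rd("qaly_weights"), manifest = manifest),
            class = "ssb_bundle")
}

#' Read a scenario configuration file
#'
#' YAML key-value file with any of `tax_per_oz`, `pass_through`,
#' `baseline_price_per_oz`, `discount_rate`, `admin_share`; unspecified keys
#' take the [tax_scenario()] defaults.
#'
#' @param path path to a YAML file.
#' @return a [tax_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("tax_per_oz", "pass_through", "baseline_price_per_oz",
             "discount_rate", "admin_share")
  do.call(tax_scenario, cfg[intersect(names(cfg), known)])
}
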