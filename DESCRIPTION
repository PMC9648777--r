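Package: ssbmslt
Title: Proportional Multi-State Life-Table Simulation of a Sugar-Sweetened
    Beverage Tax
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A proportional multi-state life-table (MSLT) Markov cohort model
    for evaluating volumetric taxes on sugar-sweetened beverages (SSBs) from a
    public health-care payer perspective. The pipeline converts a tax design
    into a price change, applies own- and cross-price elasticities of demand to
    obtain sustained changes in SSB and total energy intake, translates these
    into body-mass-index shifts via a steady-state energy balance relation,
    computes potential impact fractions on chronic-disease incidence over
    continuous risk-factor distributions, runs a four-state
    (healthy/diseased/dead-from-disease/dead-other) disease model per disease
    and age-sex cohort, and aggregates survivorship into DALYs, QALYs,
    health-care cost offsets, tax revenue and incremental cost-effectiveness
    ratios, with probabilistic (Monte Carlo) uncertainty and univariate
    sensitivity scenarios. All inputs are synthetic, internally consistent
    Canada-like tables generated by the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
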