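#!/usr/bin/env Rscript
# Step 1: fabricate the Canada-like input bundle and write it to disk.
# All downstream steps read from results/inputs/.

suppressPackageStartupMessages(library(ssbmslt))

cfg <- synthetic_config(seed = 1)
bundle <- generate_inputs(cfg)

violations <- validate_inputs(bundle)
stopifnot(nrow(violations) == 0)

dir.create("results", showWarnings = FALSE)
write_bundle(bundle, "results/inputs")

message("Synthetic bundle written to results/inputs/")
message(sprintf("  population: %s adults aged %d-%d (scale %.0e)",
                format(round(sum(bundle$population$population)), big.mark = ","),
                min(bundle$population$age), max(bundle$population$age),
                cfg$pop_scale))
message(sprintf("  diseases: %d (direct SSB pathway: %s)",
                nrow(bundle$diseases),
                paste(bundle$diseases$disease[bundle$diseases$direct_pathway],
                      collapse = ", ")))
message(sprintf("  SSB own-price elasticity: %.2f (alternative %.2f)",
                bundle$elasticity$values["ssb", "ssb"],
                bundle$elasticity_alt$values["ssb", "ssb"]))
message("  input validation: clean")
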