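#!/usr/bin/env Rscript
# In-silico emulation of the engineered strain series: GABA-1..6
# (GAD cassette; Ptuf-acn; Ptuf-icd; delta-sucCD with glyoxylate
# activation; delta-gabTD; gabP::potE) and BLM-1..3 (the same lineage
# with the acetyl-CoA-dependent butyrolactam branch, evaluated on
# butyrolactam export).

suppressPackageStartupMessages(library(gabaflux))
dir.create("results", showWarnings = FALSE)

producer <- add_gaba_pathway(build_core_model())
wt <- pfba(producer, "BIOMASS")
series <- load_strain_series(model = producer, reference_state = wt)
tab <- strain_series(producer, series,
                     production_constraint("EX_gaba", 0.2))

print(tab, row.names = FALSE, digits = 5)
write_flux_tsv(tab, "results/strain_series.tsv")

cat("\nnotes:\n")
cat("- the sucCD deletant (GABA-4) keeps growing: AKGDH still serves the\n")
cat("  succinyl-CoA biomass demand and anaplerosis regenerates OAA;\n")
cat("- shunt and transporter edits (GABA-5/6) cannot raise the FBA\n")
cat("  optimum (deletions only shrink the feasible set); their in-vivo\n")
cat("  benefit is kinetic/regulatory, outside the stoichiometric model;\n")
cat("- BLM product fluxes are lower than GABA fluxes: each butyrolactam\n")
cat("  additionally consumes one acetyl-CoA.\n")
cat("\nwrote results/strain_series.tsv\n")
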