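#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the structure of a multi-study comparative venomics dataset:
# 60 species on a dated Yule tree, 1-4 venomic records per species (Dirichlet
# compositions over 12 toxin families whose expected Shannon diversity tracks
# a species-level trait), and per-species diet record tables over 15 prey
# families nested in 8 orders. The true diet effect on venom diversity is a
# slope of 0.15 on the Shannon scale.

library(venomdiv)

outdir <- file.path("results", "bundle")
scenario <- synthetic_scenario(seed = 20260926)
bundle <- write_scenario_bundle(scenario, outdir)

cat("Synthetic bundle written to", outdir, "\n")
cat(sprintf("  species: %d, venomic records: %d, diet rows: %d\n",
            scenario$n_species,
            length(unique(bundle$records$venom$record_id)),
            nrow(bundle$records$diet)))
cat(sprintf("  true slope b1 = %.3f, intercept b0 = %.3f (%s index)\n",
            scenario$b1, scenario$b0, scenario$index))
cat(sprintf("  record-level diversity targets clipped: %d\n",
            bundle$records$n_clipped_targets))
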