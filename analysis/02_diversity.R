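#!/usr/bin/env Rscript
# Stage 2: clean the venomic records, aggregate and filter the diet records,
# and tabulate per-record venom diversity joined with species-level diet
# diversity at both taxonomic levels.

library(venomdiv)

bundle <- file.path("results", "bundle")
profiles <- read_venom_profiles(file.path(bundle, "venom.csv"))
cleaned <- clean_venom_profiles(profiles)
cat(sprintf("Venom: %d records read, %d removed for implausible totals\n",
            cleaned$report$n_input, cleaned$report$n_removed_abundance))

diet <- read_diet_records(file.path(bundle, "diet.csv"))
tables <- list()
for (lev in c("family", "order")) {
  filt <- filter_diet(aggregate_diet(diet, lev))
  tables[[lev]] <- filt$tables
  cat(sprintf("Diet (%s level): %d species, %d removed with <5 records\n",
              lev, filt$report$n_input, filt$report$n_removed_diet))
}

div <- diversity_table(cleaned$profiles, tables$family, tables$order)
cat(sprintf("Diversity table: %d records across %d species\n",
            nrow(div), length(unique(div$species))))

dir.create("results", showWarnings = FALSE)
utils::write.table(div, file.path("results", "diversity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/diversity.tsv\n")
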