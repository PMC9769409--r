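#!/usr/bin/env Rscript
# Stage 2: community-level description of the screening campaign -- trait
# prevalence, antagonism spectrum, value extremes -- bundled into one
# campaign report.

suppressPackageStartupMessages(library(pgpscreen))
dir.create("results", showWarnings = FALSE)

roster <- read_roster(pgp_fixture("roster"))
traits <- read_trait_table(pgp_fixture("traits"))
inhibition <- read_inhibition_matrix(pgp_fixture("inhibition"))

prev <- trait_prevalence(traits)
cat("trait prevalence (positive / 51):\n")
print(prev[, c("trait", "positive", "percentage")], row.names = FALSE)

sp <- antagonism_spectrum(inhibition)
cat("\nper-pathogen inhibitor counts:\n")
print(sp$per_pathogen, row.names = FALSE)
cat(sprintf("\n%d isolates antagonize at least one pathogen; broad-spectrum: %s\n",
            sp$n_any, paste(sp$broad_spectrum, collapse = ", ")))

ex <- value_extremes(traits, inhibition)
cat(sprintf("top IAA producer: %s (%.1f ug/ml)\n",
            ex$iaa$max$isolates, ex$iaa$max$value))
cat(sprintf("top phosphate solubilizer: %s (%.1f ug/ml)\n",
            ex$p_solub$max$isolates, ex$p_solub$max$value))
cat(sprintf("strongest inhibition: %s vs %s (%.1f%%)\n",
            ex$inhibition$max$pairs$isolate_id[1],
            ex$inhibition$max$pairs$pathogen[1], ex$inhibition$max$value))

report <- campaign_report(roster, traits, inhibition)
write_report_json(report, "results/campaign_report.json")
utils::write.csv(prev, "results/trait_prevalence.csv", row.names = FALSE)
cat("wrote results/campaign_report.json and results/trait_prevalence.csv\n")
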