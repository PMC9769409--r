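#!/usr/bin/env Rscript
# Stage 1: load the packaged campaign tables (roster, trait table,
# inhibition matrix) and cross-validate them. The published tables are not
# fully consistent with each other; this stage documents exactly where.

suppressPackageStartupMessages(library(pgpscreen))
dir.create("results", showWarnings = FALSE)

roster <- read_roster(pgp_fixture("roster"))
traits <- read_trait_table(pgp_fixture("traits"))
inhibition <- read_inhibition_matrix(pgp_fixture("inhibition"))

cat(sprintf("loaded %d roster rows, %d trait profiles, %d x %d inhibition matrix\n",
            nrow(roster), nrow(traits), nrow(inhibition), ncol(inhibition)))

report <- validate_roster(roster, traits, inhibition)
print(report)
write_report_json(report, "results/validation_report.json")

# Expected finding: the roster and the trait/inhibition tables disagree on
# one isolate code each way (MORA2 only in the roster, DMLA1 only in the
# trait and inhibition tables); no out-of-range values anywhere.
cat("wrote results/validation_report.json\n")
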