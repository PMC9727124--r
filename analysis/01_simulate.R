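#!/usr/bin/env Rscript
# Step 1 — simulate the two study cohorts.
#
# A discovery cohort (n = 60, 2000 genes) with the full planted 2x2 immune
# structure, and a CPI-exposed validation cohort (n = 45, three observed
# classes, IIL-FH absent) with response labels. Everything downstream reads
# the plain-text exports written here, so the whole workflow also exercises
# the file interfaces.

suppressPackageStartupMessages(library(immunoclass))

seed <- 20220
dir.create("results", showWarnings = FALSE)

disc_spec <- cohort_spec(seed = seed)
discovery <- generate_cohort(disc_spec)
write_cohort(discovery, "results/discovery_cohort")

external <- generate_external_cohort(cohort_spec(seed = seed + 1))
write_cohort(external, "results/external_cohort")

cat("Discovery cohort:", nrow(discovery$expr$values), "genes x",
    ncol(discovery$expr$values), "samples\n")
print(table(discovery$truth$combined))
cat("\nExternal CPI-exposed cohort:", nrow(external$annotations),
    "patients;", sum(external$annotations$response == "responder"),
    "responders; observed classes:",
    paste(sort(unique(external$truth$combined)), collapse = ", "), "\n")
cat("\nWritten to results/discovery_cohort and results/external_cohort\n")
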