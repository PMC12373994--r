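#!/usr/bin/env Rscript
# Recompute the published cohort table's group-difference statistics from
# its printed summary data (means/SDs/counts) and compare to the printed
# test statistics.

suppressMessages(library(cb1pet))
dir.create("results", showWarnings = FALSE)

checks <- cohort_table_checks(include_nonreproducible = TRUE)
write.csv(checks, "results/cohort_table_checks.csv", row.names = FALSE)
print(checks)
repro <- checks[!is.na(checks$pass), ]
cat(sprintf("\n%d/%d reproducible rows match within |diff| <= max(0.02, 1%%)\n",
            sum(repro$pass), nrow(repro)))
cat("Rows with pass = NA are known not to reproduce from printed summaries\n",
    "(likely computed on slightly different n or unrounded data) and are\n",
    "reported for transparency only.\n")
cat("written: results/cohort_table_checks.csv\n")
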