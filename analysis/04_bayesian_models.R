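#!/usr/bin/env Rscript
# The three Bayesian robust-regression families on the default synthetic
# cohort's true V_T values: confound models, group models with sex
# interactions, and the 13 single-cluster symptom models. Writes report
# report tables (one row per coefficient of interest).

suppressMessages(library(cb1pet))
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_config(), seed = 1)
suite <- run_model_suite(cohort, seed = 1)

write.csv(suite$confounds, "results/confound_models.csv", row.names = FALSE)
write.csv(suite$group, "results/group_models.csv", row.names = FALSE)
write.csv(suite$symptom, "results/symptom_models.csv", row.names = FALSE)

print(suite)
robust <- subset(suite$symptom, robust)
cat("Robust symptom associations (89% HPD excludes 0):",
    if (nrow(robust)) paste(robust$measure, collapse = ", ") else "none", "\n")
anh <- subset(suite$symptom, measure == "Anhedonia/Emotional Numbing")
cat(sprintf("Anhedonia/emotional-numbing slope: %.4f [%.4f, %.4f] (planted 0.014)\n",
            anh$mean, anh$hpd_low, anh$hpd_high))
cat("Note: with ~46 trauma-exposed subjects the posterior SD of this slope",
    "is close to the\nplanted effect itself, so single-cohort detection has",
    "limited power; the effect is\nreliably recovered at larger n (see the",
    "test suite's 500-subject recovery check).\n")
cat("written: results/confound_models.csv, group_models.csv, symptom_models.csv\n")
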