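#!/usr/bin/env Rscript
# Diagnostic accuracy of the five candidate tests against the any-HAI
# reference standard: on the simulated cohort, and rebuilt from the
# reference confusion counts for comparison.

library(neohai)

aug <- read_episodes("results/cohort_classified.csv")
truth_chr <- tolower(aug$any_hai)
keep <- truth_chr %in% c("true", "false", "1", "0")
aug <- aug[keep, ]
truth <- truth_chr[keep] %in% c("true", "1")

calls <- test_positivity_all(aug)
counts <- do.call(rbind, lapply(names(calls), function(t) {
  cm <- confusion_matrix(calls[[t]], truth)
  data.frame(test = t, tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
             n_excluded = cm$n_excluded)
}))

cohort_tab <- metrics_table(counts)
reference_tab <- metrics_table(reference_test_counts())
write.csv(cohort_tab, "results/metrics_cohort.csv", row.names = FALSE)
write.csv(reference_tab, "results/metrics_reference.csv", row.names = FALSE)

cat("accuracy on the simulated cohort:\n")
print(cohort_tab, row.names = FALSE)
cat("\naccuracy rebuilt from the reference counts:\n")
print(reference_tab, row.names = FALSE)
cat("\nwrote results/metrics_cohort.csv and results/metrics_reference.csv\n")
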