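#!/usr/bin/env Rscript
# Apply the reference-standard case definitions (proven / presumed / no HAI,
# with CoNS adjudication) to every episode and append the labels.

library(neohai)

cohort <- read_episodes("results/cohort.csv")
cl <- classify_hai(cohort)
aug <- cbind(cohort, cl)
write_episodes(aug, "results/cohort_classified.csv")

tab <- table(factor(cl$hai_label, c("proven", "presumed", "none",
                                    "unclassifiable")))
cat("reference-standard classification:\n")
print(tab)
cat(sprintf("any HAI: %d/%d (%.1f%%)\n", sum(cl$any_hai, na.rm = TRUE),
            nrow(cohort),
            100 * mean(cl$any_hai, na.rm = TRUE)))
if ("hai_class_sampled" %in% names(cohort)) {
  cat(sprintf("agreement with generator truth: %.1f%%\n",
              100 * mean(cl$hai_label == cohort$hai_class_sampled)))
}
cat("wrote results/cohort_classified.csv\n")
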