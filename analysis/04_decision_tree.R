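#!/usr/bin/env Rscript
# Grow the exhaustive-CHAID tree over the banded NeoHoP score (0 / 1 / >= 2)
# and the t24 CRP call; this is the tree the bedside tool is derived from.

library(neohai)

aug <- read_episodes("results/cohort_classified.csv")
truth_chr <- tolower(aug$any_hai)
keep <- truth_chr %in% c("true", "false", "1", "0")
aug <- aug[keep, ]
truth <- truth_chr[keep] %in% c("true", "1")

sc <- compute_neohop(aug)
feats <- data.frame(
  neohop_band = ifelse(is.na(sc$total), NA,
                       ifelse(sc$total >= 2, "2+", as.character(sc$total))),
  crp_t24_pos = crp_positive(aug$crp_t24),
  stringsAsFactors = FALSE)
ok <- !is.na(feats$neohop_band)

tree <- grow_tree(feats[ok, ], truth[ok], chaid_config())
writeLines(format_chaid(tree), "results/chaid_tree.txt")
writeLines(jsonlite::toJSON(chaid_to_list(tree), auto_unbox = TRUE,
                            pretty = TRUE, digits = NA),
           "results/chaid_tree.json")

cat("exhaustive-CHAID tree (any-HAI outcome):\n")
print(tree)
cat("\nwrote results/chaid_tree.txt and results/chaid_tree.json\n")
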