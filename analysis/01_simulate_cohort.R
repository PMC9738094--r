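#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Builds the default synthetic pan-cancer cohort: two reference types (REF1,
# REF2, standing in for the breast and ovarian cohorts) and eight further
# types of which C01 and C02 carry planted BRCAness signal across all six
# features. Writes every cohort table under results/cohort/ plus the planted
# truth, so each later step can run from files alone.

suppressMessages(library(brcaness))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

design <- brcaness_design(seed = seed)
gen <- generate_cohort(design)
print(gen$bundle)

paths <- write_cohort(gen$bundle, "results/cohort")
truth <- data.frame(
  gene = rep(rownames(gen$truth$plp_freq), ncol(gen$truth$plp_freq)),
  cancer_type = rep(colnames(gen$truth$plp_freq),
                    each = nrow(gen$truth$plp_freq)),
  plp_freq = as.vector(gen$truth$plp_freq),
  homdel_freq = as.vector(gen$truth$homdel_freq),
  meth_beta = as.vector(gen$truth$meth_beta),
  expr_shift = as.vector(gen$truth$expr_shift),
  hazard = as.vector(gen$truth$hazard)
)
data.table::fwrite(truth, "results/cohort/truth.tsv", sep = "\t")
writeLines(attr(design, "high_types"), "results/cohort/high_types.txt")

cat("cohort written to results/cohort/ (seed", seed, ")\n")
cat("planted BRCAness-high types:",
    paste(attr(design, "high_types"), collapse = ", "), "\n")
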