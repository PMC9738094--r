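#!/usr/bin/env Rscript
# Step 5: differential expression.
#
# Tumor-vs-normal Wilcoxon rank-sum tests per gene within each cancer type
# that has at least 5 normal samples, BH adjustment across the panel genes
# within the type, and DEG calls at adjusted p < 0.01 with at least two-fold
# change (linear scale).

suppressMessages(library(brcaness))

panel <- load_default_panel()
expr <- read_expression("results/cohort/expression.tsv")
samples <- read_sample_map("results/cohort/samples.tsv")

degs <- call_degs(expr, samples, panel)
dir.create("results/deg", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(degs$results, "results/deg/deg_results.tsv", sep = "\t")
data.table::fwrite(degs$counts, "results/deg/deg_counts.tsv", sep = "\t")
print(degs$counts)
if (length(degs$skipped)) {
  cat("types skipped for lack of normals:",
      paste(degs$skipped, collapse = ", "), "\n")
}
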