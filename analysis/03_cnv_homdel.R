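#!/usr/bin/env Rscript
# Step 3: homozygous deletions.
#
# Computes per-gene per-cancer-type homozygous-deletion frequencies from the
# GISTIC-coded copy-number matrix (code -2 only), correlates them with
# BRCA1/2 across cancer types (|r| > 0.4 rule), and compares every gene's
# pooled deletion rate against the two references.

suppressMessages(library(brcaness))

panel <- load_default_panel()
cnv <- read_cnv("results/cohort/cnv.tsv")
samples <- read_sample_map("results/cohort/samples.tsv")

fm <- homdel_frequency(cnv, samples, panel)
dir.create("results/cnv", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(data.frame(gene = rownames(fm$freq), fm$freq,
                              check.names = FALSE),
                   "results/cnv/homdel_frequency.tsv", sep = "\t")

cors <- correlate_homdel(fm, panel, threshold = 0.4)
data.table::fwrite(cors, "results/cnv/homdel_correlation.tsv", sep = "\t")

cls <- classify_vs_references(fm, panel)
data.table::fwrite(cls, "results/cnv/homdel_vs_references.tsv", sep = "\t")
counts <- attr(cls, "counts")
cat(sprintf("genes below BRCA1 pooled rate: %d; below BRCA2: %d\n",
            counts[["n_lower_than_BRCA1"]], counts[["n_lower_than_BRCA2"]]))

burden <- cancer_homdel_burden(fm, panel)
data.table::fwrite(burden, "results/cnv/homdel_burden_by_type.tsv", sep = "\t")
cat("per-type deletion burden (mean and sum) written\n")
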