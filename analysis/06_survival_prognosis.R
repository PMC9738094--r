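#!/usr/bin/env Rscript
# Step 6: survival screening.
#
# Median-split Kaplan-Meier comparison of every panel gene within every
# cancer type: two-sided log-rank p, hazard ratio (high vs low expression)
# with 95% CI in a forest-table layout, per-type risky-gene counts, and a
# 2-group stratification of one cancer type's patients on panel expression.

suppressMessages(library(brcaness))

panel <- load_default_panel()
expr <- read_expression("results/cohort/expression.tsv")
samples <- read_sample_map("results/cohort/samples.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")

scr <- prognostic_screen(expr, clinical, samples, panel)
dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(scr$results, "results/survival/forest_table.tsv",
                   sep = "\t")
data.table::fwrite(scr$risky_counts, "results/survival/risky_counts.tsv",
                   sep = "\t")
print(scr$risky_counts)

# stratify the first planted high-signal type into lower/higher groups
t1 <- readLines("results/cohort/high_types.txt")[1]
ids <- intersect(clinical$sample[clinical$cancer_type == t1], colnames(expr))
st <- stratify_patients(expr[, ids], panel, k = 2)
cat(sprintf("%s stratification: %d lower / %d higher (separation %.2f)\n",
            t1, st$sizes[["lower"]], st$sizes[["higher"]], st$separation))
cl <- clinical[match(ids, clinical$sample), ]
lr <- logrank_test(cl$os_days, cl$os_event, st$groups[ids])
cat(sprintf("lower vs higher overall survival: log-rank p = %.3g\n", lr$p))
groups <- data.frame(sample = ids, group = as.character(st$groups[ids]))
data.table::fwrite(groups, "results/survival/stratification.tsv", sep = "\t")
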