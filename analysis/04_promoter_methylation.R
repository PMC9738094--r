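#!/usr/bin/env Rscript
# Step 4: promoter methylation.
#
# Assigns probes to promoters (TSS +/- 10 kb, boundary inclusive), computes
# mean promoter betas per gene per cancer type with hypermethylation calls
# (mean > 0.3), the per-type methylation load over the 40 BRCAness genes, and
# the per-sample methylation-expression association (silencing when
# r <= -0.5).

suppressMessages(library(brcaness))

panel <- load_default_panel()
meth <- read_methylation("results/cohort/methylation_beta.tsv",
                         "results/cohort/probe_manifest.tsv")
expr <- read_expression("results/cohort/expression.tsv")
samples <- read_sample_map("results/cohort/samples.tsv")

pm <- assign_promoter_probes(meth$manifest, panel)
cat(nrow(pm), "probe-gene promoter assignments\n")

prof <- promoter_means(meth, pm, samples, panel)
dir.create("results/methylation", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(data.frame(gene = rownames(prof$mean), prof$mean,
                              check.names = FALSE),
                   "results/methylation/promoter_means.tsv", sep = "\t")
cat(sum(prof$hyper, na.rm = TRUE), "hypermethylated gene-type cells\n")

load_tab <- methylation_load(prof, panel)
data.table::fwrite(load_tab, "results/methylation/methylation_load.tsv",
                   sep = "\t")
print(load_tab[, c("cancer_type", "load")])

assoc <- methylation_expression_association(meth, pm, expr, samples, panel)
data.table::fwrite(assoc, "results/methylation/expression_association.tsv",
                   sep = "\t")
cat(sum(assoc$call == "silencing", na.rm = TRUE), "silencing calls,",
    sum(assoc$call == "enhancing", na.rm = TRUE), "enhancing calls\n")
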