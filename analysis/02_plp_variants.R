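#!/usr/bin/env Rscript
# Step 2: pathogenic / likely-pathogenic (PLP) variants.
#
# Filters the cohort's variant calls to passing non-silent rows, matches them
# against the ClinVar/COSMIC-style pathogenicity catalog at allele level,
# computes per-gene per-cancer-type carrier frequencies for each origin, and
# correlates every BRCAness gene's frequencies with BRCA1/2 across cancer
# types (|r| > 0.5 and p < 0.05 counted as significantly correlated).

suppressMessages(library(brcaness))

bundle <- load_cohort(list(
  variants = "results/cohort/variants.tsv",
  catalog = "results/cohort/catalog.tsv",
  cnv = "results/cohort/cnv.tsv",
  methylation = "results/cohort/methylation_beta.tsv",
  manifest = "results/cohort/probe_manifest.tsv",
  expression = "results/cohort/expression.tsv",
  clinical = "results/cohort/clinical.tsv",
  samples = "results/cohort/samples.tsv"
))

filtered <- filter_variants(bundle$variants)
matched <- match_plp(filtered, bundle$catalog)
cat(nrow(matched), "PLP-matched variant rows of", nrow(bundle$variants), "\n")

s <- summarize_plp(matched[matched$origin == "somatic", ],
                   matched[matched$origin == "germline", ],
                   n_types = length(unique(bundle$samples$cancer_type)))
cat(sprintf("totals: %d somatic / %d germline; per-type means %d / %d\n",
            s$total_somatic, s$total_germline,
            s$mean_somatic_rounded, s$mean_germline_rounded))

dir.create("results/plp", showWarnings = FALSE, recursive = TRUE)
for (origin in c("somatic", "germline")) {
  fm <- plp_frequency(matched, bundle$samples, bundle$panel, origin = origin)
  tab <- data.frame(gene = rownames(fm$freq), fm$freq, check.names = FALSE)
  data.table::fwrite(tab, sprintf("results/plp/%s_frequency.tsv", origin),
                     sep = "\t")
  cors <- correlate_with_references(fm, bundle$panel, threshold = 0.5)
  data.table::fwrite(cors, sprintf("results/plp/%s_correlation.tsv", origin),
                     sep = "\t")
  cat(sprintf("%s: %d gene-reference pairs significantly correlated\n",
              origin, sum(cors$significant)))
}
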