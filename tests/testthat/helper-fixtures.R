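# Fixtures built in code at test time; nothing binary on disk.

toy_panel <- function() {
  gene_panel(
    symbol = c("GENEA", "GENEB", "BRCA1", "BRCA2"),
    is_reference = c(FALSE, FALSE, TRUE, TRUE),
    tss_chrom = c("chr1", "chr1", "chr17", "chr13"),
    tss_pos = c(100000L, 500000L, 43125483L, 32315474L)
  )
}

toy_samples <- function(n_per_type = 4L, types = c("TA", "TB")) {
  ids <- unlist(lapply(types, function(t) sprintf("%s-%02d", t, 1:n_per_type)))
  data.frame(sample = ids, cancer_type = rep(types, each = n_per_type),
             sample_type = "tumor", stringsAsFactors = FALSE)
}

toy_variant_row <- function(sample = "TA-01", cancer_type = "TA",
                            gene = "GENEA", chrom = "chr1", pos = 100500L,
                            ref = "A", alt = "T",
                            classification = "Missense_Mutation",
                            filter = "PASS", origin = "somatic") {
  data.frame(sample = sample, cancer_type = cancer_type, gene = gene,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             classification = classification, filter = filter,
             origin = origin, stringsAsFactors = FALSE)
}

# 10-row toy: 4 silent, 1 failing filter, 5 passing non-silent
toy_variants_10 <- function() {
  rbind(
    toy_variant_row(classification = "Silent"),
    toy_variant_row(sample = "TA-02", classification = "Silent"),
    toy_variant_row(sample = "TA-03", classification = "Intron"),
    toy_variant_row(sample = "TA-04", classification = "3'UTR"),
    toy_variant_row(sample = "TB-01", filter = "artifact"),
    toy_variant_row(sample = "TB-01"),
    toy_variant_row(sample = "TB-02", classification = "Nonsense_Mutation"),
    toy_variant_row(sample = "TB-03", classification = "Frame_Shift_Del",
                    ref = "AT", alt = "A"),
    toy_variant_row(sample = "TB-04", classification = "Splice_Site"),
    toy_variant_row(sample = "TA-01", gene = "BRCA1", chrom = "chr17",
                    pos = 43125999L, origin = "germline")
  )
}

toy_catalog <- function() {
  pathogenicity_catalog(data.frame(
    chrom = c("chr1", "chr1", "chr17"),
    pos = c(100500L, 100600L, 43125999L),
    ref = c("A", "G", "A"), alt = c("T", "C", "T"),
    gene = c("GENEA", "GENEA", "BRCA1"),
    clinical_significance = c("Pathogenic", "Likely pathogenic", "Pathogenic"),
    source = c("clinvar", "clinvar", "cosmic"),
    stringsAsFactors = FALSE
  ))
}

# small full bundle with planted structure, cached per test file run
small_design <- function(seed = 42L) {
  panel <- load_default_panel()
  null_design(n_types = 4L, n_per_type = 20L, seed = seed, panel = panel,
              n_normal = 6L)
}
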