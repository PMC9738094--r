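# Homozygous-deletion frequencies from GISTIC-coded gene-level copy number,
# their correlation with BRCA1/2, and the per-gene comparison against the
# reference genes' pooled deletion rates.

#' Homozygous-deletion frequency per gene per cancer type
#'
#' A deletion is a GISTIC code of exactly -2; code -1 (hemizygous loss) never
#' counts. Frequency = deleted tumor samples / tumor samples of the type;
#' types without samples give missing cells. `$pan` holds the pan-cancer
#' pooled fraction per gene used by [classify_vs_references()].
#'
#' @param cnv gene x sample integer matrix of GISTIC codes.
#' @param samples sample map.
#' @param panel gene panel (rows of the result; genes absent from `cnv` give
#'   missing cells).
#' @return A `frequency_matrix`.
#' @export
homdel_frequency <- function(cnv, samples, panel) {
  validate_cnv(cnv)
  tumors <- samples[samples$sample_type == "tumor", , drop = FALSE]
  use <- intersect(colnames(cnv), tumors$sample)
  cnv <- cnv[, use, drop = FALSE]
  type_of <- tumors$cancer_type[match(use, tumors$sample)]
  types <- sort(unique(tumors$cancer_type))
  den_by_type <- vapply(types, function(t) sum(type_of == t), integer(1))
  num <- matrix(NA_integer_, nrow(panel), length(types),
                dimnames = list(panel$symbol, types))
  present <- match_panel_gene(rownames(cnv), panel)
  for (i in which(!is.na(present))) {
    g <- present[i]
    del <- cnv[i, ] == -2L
    num[g, ] <- vapply(types, function(t) sum(del[type_of == t]), integer(1))
  }
  pan_num <- rowSums(num)
  out <- new_frequency_matrix(num, den_by_type, pan_num, length(use))
  # genes without CNV data: missing, not zero
  out$freq[is.na(num)] <- NA_real_
  out
}

#' Correlate homozygous-deletion frequencies with the reference genes
#'
#' Same contract as [correlate_with_references()] but with the deletion
#' default |r| threshold of 0.4.
#'
#' @inheritParams correlate_with_references
#' @return Data frame: gene, reference, n, r, p, significant, defined.
#' @export
correlate_homdel <- function(freq, panel, threshold = 0.4, p_cutoff = 0.05) {
  correlate_with_references(freq, panel, threshold = threshold,
                            p_cutoff = p_cutoff)
}

#' Compare each gene's pooled deletion rate against the references
#'
#' Uses the pan-cancer pooled fraction per gene (all tumor samples pooled) and
#' flags, for every non-reference gene, whether its rate is strictly lower
#' than each reference gene's rate ("lower than" is strict: a tie is not
#' lower). Whenever the second reference's rate is at least the first's, the
#' genes lower than the first are a subset of those lower than the second.
#'
#' @param freq a `frequency_matrix` from [homdel_frequency()].
#' @param panel gene panel.
#' @return Data frame gene, freq, lower_than_<ref1>, lower_than_<ref2>;
#'   attribute `counts` holds the two totals and the reference rates.
#' @export
classify_vs_references <- function(freq, panel) {
  refs <- panel$symbol[panel$is_reference]
  pan <- freq$pan
  ref_rate <- setNames(pan$freq[match(refs, pan$gene)], refs)
  out <- pan[!(pan$gene %in% refs), c("gene", "freq")]
  for (ref in refs) {
    out[[paste0("lower_than_", ref)]] <- out$freq < ref_rate[[ref]]
  }
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    setNames(colSums(out[, paste0("lower_than_", refs)], na.rm = TRUE),
             paste0("n_lower_than_", refs)),
    setNames(ref_rate, paste0("rate_", refs))
  )
  out
}

#' Per-cancer-type deletion burden across the non-reference genes
#'
#' The aggregation behind a cancer-type-level deletion comparison is not
#' uniquely defined, so both the mean and the sum of per-gene frequencies
#' over the non-reference genes are reported, labeled.
#'
#' @param freq a `frequency_matrix` from [homdel_frequency()].
#' @param panel gene panel.
#' @return Data frame cancer_type, mean_freq, sum_freq, n_genes.
#' @export
cancer_homdel_burden <- function(freq, panel) {
  nonref <- panel$symbol[!panel$is_reference]
  sub <- freq$freq[nonref, , drop = FALSE]
  data.frame(
    cancer_type = colnames(sub),
    mean_freq = colMeans(sub, na.rm = TRUE),
    sum_freq = colSums(sub, na.rm = TRUE),
    n_genes = colSums(is.finite(sub)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
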