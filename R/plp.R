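# Pathogenic / likely-pathogenic (PLP) variant identification, carrier
# frequencies per gene per cancer type, and Pearson correlation of BRCAness
# gene frequencies with the BRCA1/2 references.

#' Filter variants to passing, non-silent calls
#'
#' Keeps rows whose FILTER status is "PASS" and whose classification lies in
#' the configured non-silent set. Rows with a classification outside the
#' recognised MAF vocabulary are flagged, excluded and logged. Row
#' accounting (accepted / rejected / flagged) is attached as attribute
#' `accounting` and logged, so no row is dropped silently.
#'
#' @param variants variant table (see [read_variants()]).
#' @param config configuration list; `nonsilent_classes` is used.
#' @return Filtered variant table.
#' @export
filter_variants <- function(variants, config = default_config()) {
  known <- c(config$nonsilent_classes, maf_silent_classes())
  unknown <- !(variants$classification %in% known)
  if (any(unknown)) {
    bn_log("filter_variants: flagged %d row(s) with unknown classification: %s",
           sum(unknown),
           paste(unique(variants$classification[unknown]), collapse = ", "))
  }
  keep <- !unknown & variants$filter == "PASS" &
    variants$classification %in% config$nonsilent_classes
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  acct <- c(input = nrow(variants), accepted = sum(keep),
            rejected = sum(!keep & !unknown), flagged = sum(unknown))
  attr(out, "accounting") <- acct
  bn_log("filter_variants: %d in = %d accepted + %d rejected + %d flagged",
         acct[["input"]], acct[["accepted"]], acct[["rejected"]],
         acct[["flagged"]])
  out
}

#' Reduce variant alleles to their minimal representation
#'
#' Normalizes indel representation before allele-level matching: the shared
#' suffix is trimmed first, then the shared prefix (advancing `pos`), always
#' retaining at least one base on each allele. This makes differently padded
#' representations of the same indel compare equal; alignment against a
#' reference genome sequence is not performed.
#'
#' @param pos,ref,alt parallel vectors of 1-based position and alleles.
#' @return Data frame with normalized pos, ref, alt.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

allele_key <- function(chrom, pos, ref, alt) {
  n <- normalize_alleles(pos, ref, alt)
  paste(sub("^chr", "", tolower(chrom)), n$pos, n$ref, n$alt, sep = ":")
}

#' Match variants against the pathogenicity catalog
#'
#' Keeps variant rows whose (chrom, pos, ref, alt) key -- after
#' minimal-representation normalization on both sides -- occurs in the
#' catalog. Catalog keys are deduplicated across sources, so a variant
#' present in both ClinVar and COSMIC matches once.
#'
#' @param variants filtered variant table.
#' @param catalog a `pathogenicity_catalog`.
#' @return Variant table restricted to PLP matches (origin preserved).
#' @export
match_plp <- function(variants, catalog) {
  if (nrow(variants) == 0L || nrow(catalog) == 0L) {
    return(variants[integer(0), , drop = FALSE])
  }
  cat_keys <- unique(allele_key(catalog$chrom, catalog$pos, catalog$ref,
                                catalog$alt))
  keys <- allele_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  out <- variants[keys %in% cat_keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_frequency_matrix <- function(num, den_by_type, pan_num, pan_den) {
  den <- matrix(rep(den_by_type, each = nrow(num)), nrow(num),
                dimnames = dimnames(num))
  freq <- ifelse(den > 0, num / den, NA_real_)
  pan <- data.frame(gene = rownames(num), carriers = pan_num, n = pan_den,
                    freq = if (pan_den > 0) pan_num / pan_den else NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(freq = freq, num = num, den = den, pan = pan)
  class(out) <- "frequency_matrix"
  out
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d genes x %d cancer types\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

#' Carrier frequency of PLP variants per gene per cancer type
#'
#' Frequency = (distinct tumor samples with at least one PLP in the gene) /
#' (tumor samples of the cancer type). A sample with several PLPs in one
#' gene counts once. Cancer types without tumor samples give missing cells,
#' not zero. A pan-cancer pooled aggregate per gene (all tumor samples
#' pooled) is returned in `$pan`.
#'
#' @param matched PLP-matched variant table, restricted to one origin via
#'   `origin` (or pre-restricted by the caller).
#' @param samples sample map (sample, cancer_type, sample_type).
#' @param panel gene panel defining the rows of the matrix.
#' @param origin optional "somatic"/"germline" filter applied to `matched`.
#' @return A `frequency_matrix`: `freq`, `num`, `den` (gene x type) and
#'   `pan` (per-gene pooled).
#' @export
plp_frequency <- function(matched, samples, panel, origin = NULL) {
  if (!is.null(origin)) {
    matched <- matched[matched$origin == origin, , drop = FALSE]
  }
  tumors <- samples[samples$sample_type == "tumor", , drop = FALSE]
  types <- sort(unique(tumors$cancer_type))
  den_by_type <- vapply(types, function(t) sum(tumors$cancer_type == t),
                        integer(1))
  matched <- matched[matched$sample %in% tumors$sample, , drop = FALSE]
  matched$gene <- match_panel_gene(matched$gene, panel)
  matched <- matched[!is.na(matched$gene), , drop = FALSE]
  carrier <- unique(matched[, c("gene", "sample")])
  carrier$cancer_type <- tumors$cancer_type[match(carrier$sample,
                                                  tumors$sample)]
  num <- matrix(0L, nrow(panel), length(types),
                dimnames = list(panel$symbol, types))
  if (nrow(carrier)) {
    tab <- table(factor(carrier$gene, levels = panel$symbol),
                 factor(carrier$cancer_type, levels = types))
    num <- num + unclass(tab)
  }
  pan_num <- as.integer(rowSums(num))
  names(pan_num) <- panel$symbol
  new_frequency_matrix(num, den_by_type, pan_num, nrow(tumors))
}

#' Per-origin totals and per-cancer-type means of matched PLP variants
#'
#' @param somatic,germline PLP-matched variant tables for each origin.
#' @param n_types number of cancer types the totals are averaged over.
#' @return List with totals and per-type means, raw and rounded to the
#'   nearest integer (round-half-to-even, as in base `round()`).
#' @export
summarize_plp <- function(somatic, germline, n_types) {
  if (n_types == 0L) stop("summarize_plp: n_types must be positive")
  total_somatic <- nrow(somatic)
  total_germline <- nrow(germline)
  list(
    total_somatic = total_somatic,
    total_germline = total_germline,
    mean_somatic = total_somatic / n_types,
    mean_germline = total_germline / n_types,
    mean_somatic_rounded = round(total_somatic / n_types),
    mean_germline_rounded = round(total_germline / n_types),
    n_types = n_types
  )
}

#' Pearson correlation of gene frequencies with the reference genes
#'
#' For every non-reference panel gene and each reference gene (BRCA1, BRCA2
#' in the default panel), computes Pearson's r across cancer types
#' (pairwise-complete cells) with a two-sided p from the t transform on
#' n - 2 degrees of freedom. A pair is significant when p < `p_cutoff` and
#' |r| > `threshold`. Pairs with fewer than 3 complete cancer types or zero
#' variance in either vector are returned with `defined = FALSE` and are
#' never significant.
#'
#' @param freq a `frequency_matrix`.
#' @param panel gene panel.
#' @param threshold |r| cutoff (0.5 for pathogenic-variant frequencies, 0.4
#'   for homozygous deletions).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return Data frame: gene, reference, n, r, p, significant, defined.
#' @export
correlate_with_references <- function(freq, panel, threshold = 0.5,
                                      p_cutoff = 0.05) {
  refs <- panel$symbol[panel$is_reference]
  genes <- panel$symbol[!panel$is_reference]
  rows <- list()
  for (ref in refs) {
    y_all <- freq$freq[ref, ]
    for (g in genes) {
      x_all <- freq$freq[g, ]
      ok <- is.finite(x_all) & is.finite(y_all)
      n <- sum(ok)
      x <- x_all[ok]
      y <- y_all[ok]
      defined <- n >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0
      if (defined) {
        ct <- stats::cor.test(x, y, method = "pearson",
                              alternative = "two.sided")
        r <- unname(ct$estimate)
        p <- ct$p.value
      } else {
        r <- NA_real_
        p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, reference = ref, n = n, r = r, p = p,
        significant = defined && p < p_cutoff && abs(r) > threshold,
        defined = defined, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
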