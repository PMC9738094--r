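# Promoter methylation: probe-to-gene assignment in a TSS window, mean
# promoter betas and hypermethylation calls, per-cancer methylation load,
# and methylation-expression silencing/enhancing association.

norm_chrom <- function(x) sub("^chr", "", tolower(as.character(x)))

#' Assign methylation probes to gene promoters
#'
#' A probe is assigned to gene g when it lies on the same chromosome and
#' |pos - TSS_g| <= window (boundary inclusive): the promoter is the TSS
#' +/- `window` bp. One probe may map to several genes. "chr1" vs "1"
#' chromosome conventions are normalized (and logged when they differ).
#'
#' @param manifest probe manifest (probe, chrom, pos).
#' @param panel gene panel with TSS coordinates.
#' @param window promoter half-window in bp (default 10000).
#' @return Data frame probe, gene, distance (bp from TSS).
#' @export
assign_promoter_probes <- function(manifest, panel, window = 10000L) {
  mchr <- norm_chrom(manifest$chrom)
  pchr <- norm_chrom(panel$tss_chrom)
  if (!identical(mchr, as.character(manifest$chrom)) ||
      !identical(pchr, as.character(panel$tss_chrom))) {
    bn_log("assign_promoter_probes: normalized chromosome naming ('chr' prefix stripped)")
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    hit <- mchr == pchr[i] &
      abs(manifest$pos - panel$tss_pos[i]) <= window
    if (!any(hit)) return(NULL)
    data.frame(probe = manifest$probe[hit], gene = panel$symbol[i],
               distance = manifest$pos[hit] - panel$tss_pos[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(probe = character(), gene = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Mean promoter beta per gene per cancer type, with hypermethylation calls
#'
#' The gene x type mean is taken over all window probes x tumor samples of
#' the type; a gene with no window probes is missing (never zero). The
#' hypermethylation flag is strict: mean > `beta_threshold` (a mean of
#' exactly 0.3 is not hypermethylated).
#'
#' @param meth list with `beta` (probe x sample matrix); see
#'   [read_methylation()].
#' @param probe_map probe-to-gene map from [assign_promoter_probes()].
#' @param samples sample map.
#' @param panel gene panel.
#' @param beta_threshold hypermethylation cutoff on the mean beta.
#' @return A `promoter_profile`: `mean` and `hyper` gene x type matrices and
#'   a per-gene `probe_count`.
#' @export
promoter_means <- function(meth, probe_map, samples, panel,
                           beta_threshold = 0.3) {
  if (nrow(probe_map) == 0L) stop("promoter_means: empty probe map")
  beta <- meth$beta
  tumors <- samples[samples$sample_type == "tumor", , drop = FALSE]
  use <- intersect(colnames(beta), tumors$sample)
  type_of <- tumors$cancer_type[match(use, tumors$sample)]
  types <- sort(unique(type_of))
  mean_mat <- matrix(NA_real_, nrow(panel), length(types),
                     dimnames = list(panel$symbol, types))
  probe_count <- setNames(integer(nrow(panel)), panel$symbol)
  for (g in panel$symbol) {
    probes <- intersect(probe_map$probe[probe_map$gene == g], rownames(beta))
    probe_count[g] <- length(probes)
    if (!length(probes)) next
    sub <- beta[probes, use, drop = FALSE]
    mean_mat[g, ] <- vapply(types, function(t) {
      mean(sub[, type_of == t, drop = FALSE])
    }, numeric(1))
  }
  out <- list(mean = mean_mat, hyper = mean_mat > beta_threshold,
              probe_count = probe_count, beta_threshold = beta_threshold)
  class(out) <- "promoter_profile"
  out
}

#' @export
print.promoter_profile <- function(x, ...) {
  cat(sprintf("<promoter_profile> %d genes x %d cancer types (threshold %g)\n",
              nrow(x$mean), ncol(x$mean), x$beta_threshold))
  invisible(x)
}

#' Total promoter methylation level per cancer type
#'
#' The methylation load of a cancer type is the sum of per-gene mean
#' promoter betas over the non-reference genes; missing gene cells are
#' excluded and the count of included genes reported. The reference genes'
#' means are reported in separate columns.
#'
#' @param profile a `promoter_profile`.
#' @param panel gene panel.
#' @return Data frame cancer_type, load, n_genes, plus one column per
#'   reference gene.
#' @export
methylation_load <- function(profile, panel) {
  nonref <- panel$symbol[!panel$is_reference]
  refs <- panel$symbol[panel$is_reference]
  sub <- profile$mean[nonref, , drop = FALSE]
  out <- data.frame(
    cancer_type = colnames(sub),
    load = colSums(sub, na.rm = TRUE),
    n_genes = colSums(is.finite(sub)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (ref in refs) out[[ref]] <- profile$mean[ref, ]
  out
}

#' Classify genes as hyper/hypomethylated against a reference gene
#'
#' Gene-level classification on the pan-cancer mean (mean over cancer types
#' of the per-type promoter means) compared against the reference gene's
#' pan-cancer mean.
#'
#' @param profile a `promoter_profile`.
#' @param panel gene panel.
#' @param reference reference gene symbol (default "BRCA2").
#' @return Data frame gene, pan_mean, hypermethylated; attribute `counts`.
#' @export
classify_hypermethylation <- function(profile, panel, reference = "BRCA2") {
  pan <- rowMeans(profile$mean, na.rm = TRUE)
  cutoff <- pan[[reference]]
  genes <- panel$symbol[!panel$is_reference]
  out <- data.frame(gene = genes, pan_mean = pan[genes],
                    hypermethylated = pan[genes] > cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "counts") <- c(hyper = sum(out$hypermethylated, na.rm = TRUE),
                           hypo = sum(!out$hypermethylated, na.rm = TRUE),
                           cutoff = cutoff)
  out
}

#' Methylation-expression association (silencing / enhancing calls)
#'
#' Per gene per cancer type: each shared tumor sample's promoter beta is the
#' mean over that gene's window probes; Pearson's r is computed between the
#' per-sample promoter betas and the gene's expression. The call is
#' "silencing" when r <= -threshold, "enhancing" when r >= threshold,
#' "none" otherwise; fewer than 3 shared samples (or zero variance) gives an
#' undefined result (r = NA, call = NA).
#'
#' @param meth methylation list (`beta` matrix).
#' @param probe_map probe-to-gene map.
#' @param expression gene x sample expression matrix.
#' @param samples sample map.
#' @param panel gene panel.
#' @param threshold |r| cutoff for a call (default 0.5).
#' @return Data frame gene, cancer_type, n, r, call.
#' @export
methylation_expression_association <- function(meth, probe_map, expression,
                                               samples, panel,
                                               threshold = 0.5) {
  beta <- meth$beta
  tumors <- samples[samples$sample_type == "tumor", , drop = FALSE]
  shared <- intersect(intersect(colnames(beta), colnames(expression)),
                      tumors$sample)
  type_of <- tumors$cancer_type[match(shared, tumors$sample)]
  types <- sort(unique(type_of))
  rows <- list()
  for (g in intersect(panel$symbol, rownames(expression))) {
    probes <- intersect(probe_map$probe[probe_map$gene == g], rownames(beta))
    if (!length(probes)) next
    pb <- colMeans(beta[probes, shared, drop = FALSE])
    ex <- expression[g, shared]
    for (t in types) {
      sel <- type_of == t
      n <- sum(sel)
      r <- NA_real_
      if (n >= 3L && stats::sd(pb[sel]) > 0 && stats::sd(ex[sel]) > 0) {
        r <- stats::cor(pb[sel], ex[sel])
      }
      call <- if (!is.finite(r)) NA_character_
        else if (r <= -threshold) "silencing"
        else if (r >= threshold) "enhancing"
        else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cancer_type = t, n = n, r = r, call = call,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
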