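#' Construct and validate a gene panel
#'
#' A gene panel is a data frame with one row per gene: `symbol`,
#' `is_reference` (TRUE exactly for the two reference genes, BRCA1 and
#' BRCA2 in the default panel), `tss_chrom` and `tss_pos` (1-based
#' transcription start site, fully-closed coordinates as in MAF).
#'
#' @param symbol character vector of unique gene symbols.
#' @param is_reference logical vector; exactly two TRUE entries.
#' @param tss_chrom chromosome name per gene (any "chr1"/"1" convention;
#'   normalized internally when matched against probe manifests).
#' @param tss_pos 1-based TSS coordinate per gene.
#' @return A `gene_panel` data frame.
#' @export
gene_panel <- function(symbol, is_reference, tss_chrom, tss_pos) {
  panel <- data.frame(
    symbol = as.character(symbol),
    is_reference = as.logical(is_reference),
    tss_chrom = as.character(tss_chrom),
    tss_pos = as.integer(tss_pos),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  up <- toupper(panel$symbol)
  if (anyDuplicated(up)) {
    stop("gene panel symbols must be unique (case-insensitive): ",
         paste(unique(up[duplicated(up)]), collapse = ", "))
  }
  if (sum(panel$is_reference) != 2L) {
    stop("gene panel must contain exactly 2 reference genes, found ",
         sum(panel$is_reference))
  }
  if (any(is.na(panel$tss_pos)) || any(panel$tss_pos < 1L)) {
    stop("gene panel TSS positions must be positive 1-based integers")
  }
  invisible(panel)
}

#' Load the packaged default BRCAness gene panel
#'
#' The default panel holds the 40 curated BRCAness genes plus the two
#' reference genes BRCA1 and BRCA2 (42 symbols in total), with approximate
#' GRCh38 TSS coordinates from the packaged annotation table. The table
#' declares its genome build in its header; supply your own table via
#' `path` to use a different annotation.
#'
#' @param path path to a panel TSV (columns `symbol`, `is_reference`,
#'   `tss_chrom`, `tss_pos`); defaults to the packaged GRCh38 table.
#' @return A [gene_panel()] with 42 genes, 40 of them non-reference.
#' @export
load_default_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "brcaness_panel_grch38.tsv",
                        package = "brcaness")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("panel annotation table not found: ", path)
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           skip = "symbol\t", data.table = FALSE)
  required_columns(tab, c("symbol", "is_reference", "tss_chrom", "tss_pos"),
                   path)
  gene_panel(tab$symbol, tab$is_reference, tab$tss_chrom, tab$tss_pos)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes (%d reference: %s)\n",
              nrow(x), sum(x$is_reference),
              paste(x$symbol[x$is_reference], collapse = ", ")))
  NextMethod()
}

# case-insensitive symbol matching; no alias resolution
panel_symbols <- function(panel, reference = NA) {
  sel <- if (is.na(reference)) rep(TRUE, nrow(panel))
         else panel$is_reference == reference
  panel$symbol[sel]
}

match_panel_gene <- function(genes, panel) {
  idx <- match(toupper(genes), toupper(panel$symbol))
  panel$symbol[idx]
}
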