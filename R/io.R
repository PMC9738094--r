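# Readers and writers for every external table the pipeline touches.
# All genomic coordinates are 1-based, fully closed, as in MAF.

required_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(tab)
}

# on-disk MAF-dialect column names <-> in-memory short names
maf_columns <- c(
  sample = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
  chrom = "Chromosome", pos = "Start_Position",
  ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
  classification = "Variant_Classification", filter = "FILTER",
  origin = "origin"
)

#' Read a MAF-dialect variant table
#'
#' Coordinates are 1-based fully closed. The file must carry the MAF columns
#' Hugo_Symbol, Chromosome, Start_Position, Reference_Allele,
#' Tumor_Seq_Allele2, Variant_Classification, FILTER, Tumor_Sample_Barcode
#' plus an `origin` column with values "somatic"/"germline".
#'
#' @param path tab-delimited variant file.
#' @return Data frame with columns sample, gene, chrom, pos, ref, alt,
#'   classification, filter, origin (empty files with a valid header yield
#'   zero rows, not an error).
#' @export
read_variants <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE,
                           colClasses = list(character = "Chromosome"))
  required_columns(tab, unname(maf_columns), path)
  out <- tab[, unname(maf_columns)]
  names(out) <- names(maf_columns)
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  bad <- setdiff(unique(out$origin), c("somatic", "germline"))
  if (length(bad)) {
    stop("malformed header in ", path, ": column origin has values outside ",
         "{somatic, germline}: ", paste(bad, collapse = ", "))
  }
  out
}

#' Write a variant table in the MAF dialect read by [read_variants()]
#' @param variants in-memory variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- variants[, names(maf_columns)]
  names(out) <- unname(maf_columns)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a pathogenicity catalog (ClinVar/COSMIC-style PLP reference)
#'
#' Keeps only pathogenic / likely-pathogenic entries: ClinVar rows must be
#' "Pathogenic" or "Likely pathogenic", COSMIC rows "Pathogenic"; other rows
#' are rejected with a log line. Coordinates 1-based.
#'
#' @param path TSV with columns chrom, pos, ref, alt, gene,
#'   clinical_significance, source.
#' @return `pathogenicity_catalog` data frame.
#' @export
read_catalog <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE,
                           colClasses = list(character = "chrom"))
  required_columns(tab, c("chrom", "pos", "ref", "alt", "gene",
                          "clinical_significance", "source"), path)
  pathogenicity_catalog(tab)
}

#' Construct a validated pathogenicity catalog
#' @param tab data frame with chrom, pos, ref, alt, gene,
#'   clinical_significance, source columns.
#' @return `pathogenicity_catalog` data frame restricted to PLP entries.
#' @export
pathogenicity_catalog <- function(tab) {
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  ok <- (tab$source == "clinvar" &
           tab$clinical_significance %in% c("Pathogenic", "Likely pathogenic")) |
        (tab$source == "cosmic" & tab$clinical_significance == "Pathogenic")
  if (any(!ok)) {
    bn_log("catalog: rejected %d non-PLP row(s)", sum(!ok))
    tab <- tab[ok, , drop = FALSE]
  }
  key <- paste(tab$source, tab$chrom, tab$pos, tab$ref, tab$alt)
  if (anyDuplicated(key)) {
    stop("catalog keys must be unique per source; duplicated: ",
         paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  class(tab) <- c("pathogenicity_catalog", "data.frame")
  tab
}

#' @export
write_catalog <- function(catalog, path) {
  data.table::fwrite(as.data.frame(catalog), path, sep = "\t")
  invisible(path)
}

# gene x sample (or probe x sample) numeric matrix with an id column on disk
read_feature_matrix <- function(path, id_col) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  required_columns(tab, id_col, path)
  m <- as.matrix(tab[, setdiff(names(tab), id_col), drop = FALSE])
  rownames(m) <- tab[[id_col]]
  m
}

write_feature_matrix <- function(m, path, id_col) {
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- id_col
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read a GISTIC-coded gene x sample copy-number matrix
#' @param path TSV with a `gene` column then one integer column per sample;
#'   entries must be in \{-2,-1,0,1,2\} (-2 = homozygous deletion).
#' @return Integer matrix, genes in rows.
#' @export
read_cnv <- function(path) {
  m <- read_feature_matrix(path, "gene")
  validate_cnv(m)
  m
}

validate_cnv <- function(m) {
  if (!all(m %in% -2:2)) {
    stop("CNV matrix entries must be GISTIC codes in {-2,-1,0,1,2}")
  }
  invisible(m)
}

#' Read a probe x sample methylation beta matrix plus its probe manifest
#' @param beta_path TSV with a `probe` column then one beta column per sample.
#' @param manifest_path TSV probe -> chrom, pos (1-based probe coordinate).
#' @return List with `beta` matrix and `manifest` data frame.
#' @export
read_methylation <- function(beta_path, manifest_path) {
  beta <- read_feature_matrix(beta_path, "probe")
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("methylation beta values must lie in [0, 1]: ", beta_path)
  }
  manifest <- data.table::fread(manifest_path, sep = "\t", header = TRUE,
                                data.table = FALSE,
                                colClasses = list(character = "chrom"))
  required_columns(manifest, c("probe", "chrom", "pos"), manifest_path)
  manifest$pos <- as.integer(manifest$pos)
  missing <- setdiff(rownames(beta), manifest$probe)
  if (length(missing)) {
    stop("probes without manifest entry in ", beta_path, ": ",
         paste(head(missing, 5), collapse = ", "))
  }
  list(beta = beta, manifest = manifest)
}

#' Read a log2(norm+1) gene x sample expression matrix
#' @param path TSV with a `gene` column then one column per sample.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  m <- read_feature_matrix(path, "gene")
  if (any(!is.finite(m))) stop("expression values must be finite: ", path)
  m
}

#' Read the sample map (sample -> cancer type, tumor/normal flag)
#' @param path TSV with columns sample, cancer_type, sample_type.
#' @return Data frame.
#' @export
read_sample_map <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  required_columns(tab, c("sample", "cancer_type", "sample_type"), path)
  bad <- setdiff(unique(tab$sample_type), c("tumor", "normal"))
  if (length(bad)) {
    stop("sample_type must be tumor/normal in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(tab$sample)) stop("duplicate sample IDs in ", path)
  tab
}

#' Read the clinical table (overall survival)
#' @param path TSV with columns sample, cancer_type, os_days, os_event.
#' @return Data frame; os_days >= 0, os_event in \{0, 1\}.
#' @export
read_clinical <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  required_columns(tab, c("sample", "cancer_type", "os_days", "os_event"),
                   path)
  if (any(tab$os_days < 0)) stop("negative survival times in ", path)
  if (!all(tab$os_event %in% c(0, 1))) {
    stop("os_event must be 0 (censored) or 1 (death) in ", path)
  }
  tab
}

#' Assemble and validate a cohort bundle from per-table files
#'
#' Reads every cohort table, checks referential integrity (every sample seen
#' in an omics table must appear in the sample map) and flags variant rows
#' whose gene lies outside the panel (`in_panel` column; rows are retained).
#' Row accounting is logged: input rows = accepted + flagged, nothing is
#' silently dropped.
#'
#' @param paths named list of file paths: variants, catalog, cnv,
#'   methylation, manifest, expression, clinical, samples.
#' @param panel a [gene_panel()].
#' @return A `cohort_bundle` list with elements variants, catalog, cnv,
#'   methylation (beta + manifest), expression, clinical, samples, panel.
#' @export
load_cohort <- function(paths, panel = load_default_panel()) {
  need <- c("variants", "catalog", "cnv", "methylation", "manifest",
            "expression", "clinical", "samples")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop("load_cohort: missing path(s): ", paste(missing, collapse = ", "))
  }
  samples <- read_sample_map(paths$samples)
  variants <- read_variants(paths$variants)
  catalog <- read_catalog(paths$catalog)
  cnv <- read_cnv(paths$cnv)
  meth <- read_methylation(paths$methylation, paths$manifest)
  expr <- read_expression(paths$expression)
  clinical <- read_clinical(paths$clinical)

  check_samples <- function(ids, what) {
    unknown <- setdiff(unique(ids), samples$sample)
    if (length(unknown)) {
      stop("validation error: ", what, " references sample(s) absent from ",
           "the sample map: ", paste(head(unknown, 10), collapse = ", "))
    }
  }
  check_samples(variants$sample, "variant table")
  check_samples(colnames(cnv), "CNV matrix")
  check_samples(colnames(meth$beta), "methylation matrix")
  check_samples(colnames(expr), "expression matrix")
  check_samples(clinical$sample, "clinical table")

  variants$cancer_type <- samples$cancer_type[match(variants$sample,
                                                    samples$sample)]
  variants$in_panel <- !is.na(match_panel_gene(variants$gene, panel))
  n_flag <- sum(!variants$in_panel)
  bn_log("load_cohort: %d variant rows (%d in panel, %d flagged off-panel, 0 rejected)",
         nrow(variants), nrow(variants) - n_flag, n_flag)

  bundle <- list(variants = variants, catalog = catalog, cnv = cnv,
                 methylation = meth, expression = expr, clinical = clinical,
                 samples = samples, panel = panel)
  class(bundle) <- "cohort_bundle"
  bundle
}

#' Write every table of a cohort bundle to a directory
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return Named list of paths suitable for [load_cohort()].
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    variants = file.path(dir, "variants.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    cnv = file.path(dir, "cnv.tsv"),
    methylation = file.path(dir, "methylation_beta.tsv"),
    manifest = file.path(dir, "probe_manifest.tsv"),
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    samples = file.path(dir, "samples.tsv")
  )
  v <- bundle$variants
  v$in_panel <- NULL
  write_variants(v, p$variants)
  write_catalog(bundle$catalog, p$catalog)
  write_feature_matrix(bundle$cnv, p$cnv, "gene")
  write_feature_matrix(bundle$methylation$beta, p$methylation, "probe")
  data.table::fwrite(bundle$methylation$manifest, p$manifest, sep = "\t")
  write_feature_matrix(bundle$expression, p$expression, "gene")
  data.table::fwrite(bundle$clinical, p$clinical, sep = "\t")
  data.table::fwrite(bundle$samples, p$samples, sep = "\t")
  p
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("<cohort_bundle> %d samples (%d tumor) in %d cancer ",
                     "types; %d variants, %d catalog entries, %d CNV genes, ",
                     "%d probes, %d expression genes, %d clinical rows\n"),
              nrow(x$samples), sum(x$samples$sample_type == "tumor"),
              length(unique(x$samples$cancer_type)), nrow(x$variants),
              nrow(x$catalog), nrow(x$cnv), nrow(x$methylation$beta),
              nrow(x$expression), nrow(x$clinical)))
  invisible(x)
}

#' Names of the 12 normalized score columns
#' @return Character vector: the six features against each reference.
#' @export
score_column_names <- function() {
  feats <- c("somatic", "germline", "homozygotic", "methylation",
             "expression", "prognosis")
  c(paste0(feats, "_ref1"), paste0(feats, "_ref2"))
}

#' Write a normalized score table (one row per cancer type)
#'
#' Tab-delimited, 12 normalized columns plus Sum and rank; missing features
#' are rendered as "-".
#'
#' @param table scored table from [score_and_rank()] (or a normalized table;
#'   Sum/rank columns are written when present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    y <- as.character(x)
    y[is.na(x)] <- "-"
    y
  })
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a normalized score table written by [write_score_table()]
#'
#' Also reads published composite-score tables of the same shape; "-" cells
#' become NA.
#'
#' @param path tab-delimited score table.
#' @return `normalized_score_table` data frame.
#' @export
read_score_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "-",
                           skip = "cancer_type\t", data.table = FALSE)
  required_columns(tab, c("cancer_type", score_column_names()), path)
  for (col in setdiff(names(tab), "cancer_type")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  class(tab) <- c("normalized_score_table", "data.frame")
  tab
}

#' Load the packaged published composite-score table (worked example)
#'
#' A published pan-cancer reference-normalized BRCAness score table: 21
#' candidate cancer types plus the combined breast/ovarian reference row,
#' each with 12 normalized feature columns and the published Sum.
#'
#' @return `normalized_score_table` with a `sum_published` column.
#' @export
load_published_score_table <- function() {
  path <- system.file("extdata", "published_score_table.tsv",
                      package = "brcaness")
  read_score_table(path)
}
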