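# Composite BRCAness score: assemble the six per-cancer features, normalize
# each against the two reference cancer types (references = 1 per column),
# sum the 12 normalized columns, rank, and call candidate cancer types.

feature_names <- function() {
  c("somatic", "germline", "homozygotic", "methylation", "expression",
    "prognosis")
}

#' Assemble the six BRCAness features per cancer type
#'
#' Frequency features (somatic, germline, homozygotic) are the sums over the
#' non-reference panel genes of the per-gene per-type frequencies; the
#' methylation feature is the promoter methylation load; the expression
#' feature is the DEG count (missing for types the expression stage
#' skipped); the prognosis feature is the risky-gene count.
#'
#' @param plp_somatic,plp_germline `frequency_matrix` objects from
#'   [plp_frequency()] for each origin.
#' @param homdel `frequency_matrix` from [homdel_frequency()].
#' @param meth_load data frame from [methylation_load()].
#' @param degs `deg_results` from [call_degs()].
#' @param surv `survival_screen` from [prognostic_screen()].
#' @param panel gene panel.
#' @return A `feature_table` data frame: cancer_type plus the six features.
#' @export
assemble_features <- function(plp_somatic, plp_germline, homdel, meth_load,
                              degs, surv, panel) {
  nonref <- panel$symbol[!panel$is_reference]
  freq_feature <- function(fm) {
    sub <- fm$freq[nonref, , drop = FALSE]
    v <- colSums(sub, na.rm = TRUE)
    v[colSums(is.finite(sub)) == 0L] <- NA_real_
    v
  }
  somatic <- freq_feature(plp_somatic)
  germline <- freq_feature(plp_germline)
  homozygotic <- freq_feature(homdel)
  types <- sort(Reduce(union, list(names(somatic), meth_load$cancer_type,
                                   degs$counts$cancer_type,
                                   surv$risky_counts$cancer_type)))
  if (length(types) == 0L) stop("assemble_features: empty cohort")
  pick <- function(v, keys) {
    out <- setNames(rep(NA_real_, length(types)), types)
    out[keys] <- v
    out
  }
  tab <- data.frame(
    cancer_type = types,
    somatic = pick(somatic, names(somatic)),
    germline = pick(germline, names(germline)),
    homozygotic = pick(homozygotic, names(homozygotic)),
    methylation = pick(meth_load$load, meth_load$cancer_type),
    expression = pick(as.numeric(degs$counts$n_deg), degs$counts$cancer_type),
    prognosis = pick(as.numeric(surv$risky_counts$n_risky),
                     surv$risky_counts$cancer_type),
    stringsAsFactors = FALSE, row.names = NULL
  )
  n_missing <- sum(is.na(as.matrix(tab[feature_names()])))
  if (n_missing > 0L) {
    bn_log("assemble_features: %d missing feature cell(s)", n_missing)
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Normalize a feature table against the two reference cancer types
#'
#' Each of the six features is divided by its value in the first reference
#' type (columns `*_ref1`) and in the second (`*_ref2`), so the reference
#' rows are exactly 1.0 in every defined column. Missing cells stay missing.
#' Both references must have all six features defined and non-zero.
#'
#' @param features a `feature_table`.
#' @param ref1,ref2 reference cancer type labels (breast- and ovarian-like).
#' @return A `normalized_score_table` with 12 columns; attribute `refs`.
#' @export
normalize_features <- function(features, ref1, ref2) {
  feats <- feature_names()
  for (ref in c(ref1, ref2)) {
    if (!ref %in% features$cancer_type) {
      stop("normalize_features: reference type not in table: ", ref)
    }
    vals <- as.numeric(features[features$cancer_type == ref, feats])
    bad <- feats[!is.finite(vals) | vals == 0]
    if (length(bad)) {
      stop("normalize_features: reference ", ref,
           " has missing or zero feature(s): ", paste(bad, collapse = ", "))
    }
  }
  out <- data.frame(cancer_type = features$cancer_type,
                    stringsAsFactors = FALSE)
  for (i in seq_along(c(ref1, ref2))) {
    ref <- c(ref1, ref2)[i]
    ref_vals <- as.numeric(features[features$cancer_type == ref, feats])
    for (j in seq_along(feats)) {
      out[[paste0(feats[j], "_ref", i)]] <- features[[feats[j]]] / ref_vals[j]
    }
  }
  attr(out, "refs") <- c(ref1, ref2)
  class(out) <- c("normalized_score_table", "data.frame")
  out
}

#' Sum, rank and qualify the normalized score table
#'
#' Sum = the sum of the 12 normalized columns with missing cells
#' contributing 0; rank is descending by Sum (ties broken by table order, so
#' ranks are a permutation). A cancer type qualifies as a BRCAness candidate
#' when its Sum strictly exceeds the reference Sum -- 2 x the number of
#' defined features of the references, i.e. 12.0 when all six are defined.
#' Reference rows (all defined columns exactly 1) never qualify.
#' `qualify_rule = "all_columns"` instead requires every defined normalized
#' column to be >= 1.
#'
#' @param normalized a `normalized_score_table`.
#' @param ref_sum reference Sum; by default taken from the rows whose
#'   defined columns are all exactly 1 (falling back to 12).
#' @param qualify_rule "sum" (default) or "all_columns".
#' @return The table with `Sum`, `rank`, `qualifies` columns added.
#' @export
score_and_rank <- function(normalized, ref_sum = NULL,
                           qualify_rule = c("sum", "all_columns")) {
  qualify_rule <- match.arg(qualify_rule)
  cols <- score_column_names()
  m <- as.matrix(as.data.frame(normalized)[cols])
  sums <- rowSums(m, na.rm = TRUE)
  # reference rows: named by the refs attribute when the table comes from
  # normalize_features(), otherwise detected as all defined columns == 1
  # (a published table's combined reference row)
  is_ref_row <- apply(m, 1L, function(r) {
    any(is.finite(r)) && all(abs(r[is.finite(r)] - 1) < 1e-9)
  })
  refs <- attr(normalized, "refs")
  if (!is.null(refs)) {
    is_ref_row <- is_ref_row | normalized$cancer_type %in% refs
  }
  if (is.null(ref_sum)) {
    # 2 x the number of features defined for the references (12.0 when all
    # six are defined): each reference scores exactly 1 per defined column
    ref_sum <- if (!is.null(refs)) {
      ref_m <- m[normalized$cancer_type %in% refs, , drop = FALSE]
      sum(colSums(is.finite(ref_m)) == nrow(ref_m))
    } else if (any(is_ref_row)) {
      max(sums[is_ref_row])
    } else 12
  }
  out <- as.data.frame(normalized)
  out$Sum <- sums
  out$rank <- rank(-sums, ties.method = "first")
  out$qualifies <- if (qualify_rule == "sum") {
    sums > ref_sum & !is_ref_row
  } else {
    apply(m, 1L, function(r) all(r[is.finite(r)] >= 1)) & !is_ref_row
  }
  attr(out, "refs") <- attr(normalized, "refs")
  attr(out, "ref_sum") <- ref_sum
  class(out) <- c("scored_table", "normalized_score_table", "data.frame")
  out
}

#' Candidate cancer types in descending composite-score order
#'
#' @param scored table from [score_and_rank()].
#' @return The qualifying rows, ordered by decreasing Sum.
#' @export
candidate_report <- function(scored) {
  out <- scored[scored$qualifies, , drop = FALSE]
  out <- out[order(-out$Sum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full BRCAness pipeline on a cohort bundle
#'
#' Convenience driver: variant filtering and PLP matching, carrier and
#' deletion frequencies, promoter methylation profile and load, DEG calling,
#' prognostic screen, feature assembly, reference normalization, and scoring.
#'
#' @param bundle a `cohort_bundle`.
#' @param ref1,ref2 reference cancer type labels.
#' @param config configuration list.
#' @return List with every stage output plus `features`, `normalized`,
#'   `scored`, `candidates`.
#' @export
run_pipeline <- function(bundle, ref1, ref2, config = default_config()) {
  panel <- bundle$panel
  filtered <- filter_variants(bundle$variants, config)
  matched <- match_plp(filtered, bundle$catalog)
  plp_som <- plp_frequency(matched, bundle$samples, panel, origin = "somatic")
  plp_germ <- plp_frequency(matched, bundle$samples, panel,
                            origin = "germline")
  homdel <- homdel_frequency(bundle$cnv, bundle$samples, panel)
  probe_map <- assign_promoter_probes(bundle$methylation$manifest, panel,
                                      window = config$tss_window)
  profile <- promoter_means(bundle$methylation, probe_map, bundle$samples,
                            panel, beta_threshold = config$beta_threshold)
  meth_load <- methylation_load(profile, panel)
  degs <- call_degs(bundle$expression, bundle$samples, panel, config)
  surv <- prognostic_screen(bundle$expression, bundle$clinical,
                            bundle$samples, panel, config)
  features <- assemble_features(plp_som, plp_germ, homdel, meth_load, degs,
                                surv, panel)
  normalized <- normalize_features(features, ref1, ref2)
  scored <- score_and_rank(normalized, qualify_rule = config$qualify_rule)
  list(
    filtered = filtered, matched = matched,
    plp_somatic = plp_som, plp_germline = plp_germ, homdel = homdel,
    probe_map = probe_map, profile = profile, meth_load = meth_load,
    degs = degs, surv = surv, features = features, normalized = normalized,
    scored = scored, candidates = candidate_report(scored)
  )
}
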