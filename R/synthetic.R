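# Seeded synthetic pan-cancer cohorts with planted BRCAness structure.
# Every downstream stage is validated against the planted ground truth.

#' Specify a synthetic cohort design
#'
#' All planted effects are gene x cancer-type matrices over the panel genes.
#' Survival follows an exponential model whose per-sample rate is multiplied
#' by `hazard[g, t]` for every gene g whose expression exceeds the gene's
#' within-type median, with independent uniform censoring on
#' `[0, censor_max]` -- the simplest model whose true hazard ratio equals the
#' rate ratio. Methylation betas are Gaussian around the planted mean and
#' clipped to [0.01, 0.99].
#'
#' @param cancer_types character vector of cohort labels.
#' @param n_tumor integer vector (recycled) of tumor samples per type (>= 2).
#' @param reference_types two labels standing in for the breast and ovarian
#'   reference cohorts.
#' @param panel a [gene_panel()].
#' @param plp_freq gene x type carrier probability of a catalog-matching
#'   pathogenic variant; applied independently to the somatic and germline
#'   origins.
#' @param homdel_freq gene x type probability of GISTIC code -2.
#' @param meth_beta gene x type mean promoter beta in \[0, 1\].
#' @param expr_shift gene x type log2 shift of tumor vs normal expression.
#' @param hazard gene x type hazard ratio (> 0) of the high- vs
#'   low-expression group.
#' @param silencing gene x type methylation-to-expression coupling (>= 0);
#'   positive values make tumor expression fall as a sample's promoter beta
#'   rises, planting silencing correlations.
#' @param n_normal normal samples per type (recycled).
#' @param probe_noise_sd within-gene probe noise SD on the beta scale.
#' @param expr_noise_sd expression noise SD (log2 scale).
#' @param background_mut_rate Poisson mean of background (non-PLP) variants
#'   per tumor sample; classifications span silent and non-silent so filter
#'   logic is exercised.
#' @param base_event_rate baseline exponential event rate per day.
#' @param censor_max upper bound of the uniform censoring time (days).
#' @param seed integer RNG seed; identical design + seed gives identical
#'   cohorts.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(cancer_types, n_tumor, reference_types, panel,
                              plp_freq, homdel_freq, meth_beta, expr_shift,
                              hazard, silencing = NULL,
                              n_normal = 10L, probe_noise_sd = 0.05,
                              expr_noise_sd = 0.5,
                              background_mut_rate = 0.5,
                              base_event_rate = 1 / 1000,
                              censor_max = 3000, seed = 1L) {
  k <- length(cancer_types)
  n_tumor <- rep_len(as.integer(n_tumor), k)
  n_normal <- rep_len(as.integer(n_normal), k)
  if (anyDuplicated(cancer_types)) stop("cancer type labels must be unique")
  if (!all(reference_types %in% cancer_types) ||
      length(reference_types) != 2L) {
    stop("reference_types must be two of the cancer type labels")
  }
  if (any(n_tumor < 2L)) stop("design error: sample counts must be >= 2")
  shape <- function(m, what, lo = -Inf, hi = Inf) {
    if (is.null(m)) m <- matrix(0, nrow(panel), k)
    m <- matrix(as.numeric(m), nrow(panel), k,
                dimnames = list(panel$symbol, cancer_types))
    if (any(is.na(m)) || any(m < lo) || any(m > hi)) {
      stop("design error: ", what, " must lie in [", lo, ", ", hi, "]")
    }
    m
  }
  design <- list(
    cancer_types = cancer_types, n_tumor = n_tumor, n_normal = n_normal,
    reference_types = reference_types, panel = panel,
    plp_freq = shape(plp_freq, "plp_freq", 0, 1),
    homdel_freq = shape(homdel_freq, "homdel_freq", 0, 1),
    meth_beta = shape(meth_beta, "meth_beta", 0, 1),
    expr_shift = shape(expr_shift, "expr_shift"),
    hazard = shape(hazard, "hazard", lo = .Machine$double.eps),
    silencing = shape(silencing, "silencing", 0, Inf),
    probe_noise_sd = probe_noise_sd, expr_noise_sd = expr_noise_sd,
    background_mut_rate = background_mut_rate,
    base_event_rate = base_event_rate, censor_max = censor_max,
    seed = as.integer(seed)
  )
  class(design) <- "simulation_design"
  design
}

#' Null design: no planted effects, for calibration
#'
#' Uniform low-rate pathogenic-variant and deletion background, flat
#' methylation, no expression shift, hazard ratio 1 everywhere.
#'
#' @param n_types number of cancer types (first two act as references).
#' @param n_per_type tumor samples per type (>= 10).
#' @param seed RNG seed.
#' @param panel gene panel.
#' @param n_normal normal samples per type.
#' @return A `simulation_design`.
#' @export
null_design <- function(n_types = 8L, n_per_type = 50L, seed = 1L,
                        panel = load_default_panel(), n_normal = 10L) {
  if (n_per_type < 10L) stop("null_design requires n_per_type >= 10")
  types <- sprintf("SIM%02d", seq_len(n_types))
  simulation_design(
    cancer_types = types, n_tumor = n_per_type,
    reference_types = types[1:2], panel = panel,
    plp_freq = 0.02, homdel_freq = 0.01, meth_beta = 0.2,
    expr_shift = 0, hazard = 1, silencing = 0,
    n_normal = n_normal, seed = seed
  )
}

#' Default study design: two BRCAness-high types among eight, plus references
#'
#' Emulates the structure the scoring pipeline assumes: two reference types
#' (breast- and ovarian-like, moderate signal in a 10-gene core set), two
#' "BRCAness-high" types with stronger and broader signal (20 genes), and six
#' background types. Signal spans all six features: elevated carrier and
#' deletion frequencies, promoter hypermethylation with expression silencing,
#' tumor-vs-normal down-shifts beyond two-fold, and expression-dependent
#' hazards.
#'
#' @param seed RNG seed.
#' @param n_tumor tumor samples per type.
#' @param n_normal normal samples per type.
#' @param panel gene panel.
#' @return A `simulation_design`; attribute `high_types` names the two
#'   planted BRCAness-high labels.
#' @export
brcaness_design <- function(seed = 1L, n_tumor = 60L, n_normal = 10L,
                            panel = load_default_panel()) {
  types <- c("REF1", "REF2", sprintf("C%02d", 1:8))
  high <- c("C01", "C02")
  nonref_genes <- panel$symbol[!panel$is_reference]
  core <- nonref_genes[1:10]          # signal genes in references
  broad <- nonref_genes[1:20]         # signal genes in high types

  plant <- function(base, ref_core, high_broad) {
    m <- matrix(base, nrow(panel), length(types),
                dimnames = list(panel$symbol, types))
    m[core, c("REF1", "REF2")] <- ref_core
    m[broad, high] <- high_broad
    # reference genes carry signal in the reference types
    m[panel$symbol[panel$is_reference], c("REF1", "REF2")] <- ref_core
    m
  }
  design <- simulation_design(
    cancer_types = types, n_tumor = n_tumor, reference_types = c("REF1", "REF2"),
    panel = panel,
    plp_freq = plant(0.01, 0.05, 0.12),
    homdel_freq = plant(0.005, 0.03, 0.06),
    meth_beta = plant(0.15, 0.40, 0.55),
    expr_shift = plant(0, -1.8, -2.8),
    hazard = plant(1, 2.2, 3.0),
    silencing = plant(0, 1, 1),
    n_normal = n_normal, seed = seed
  )
  attr(design, "high_types") <- high
  design
}

random_bases <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(exclude)) {
    clash <- out == exclude
    while (any(clash)) {
      out[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- out == exclude
    }
  }
  out
}

# synthetic PLP catalog: a few allele-level entries per panel gene, placed
# near the gene's TSS so they are consistent with the probe manifest
synthetic_catalog <- function(panel, per_gene = 4L) {
  n <- nrow(panel) * per_gene
  gene <- rep(panel$symbol, each = per_gene)
  chrom <- rep(panel$tss_chrom, each = per_gene)
  pos <- rep(panel$tss_pos, each = per_gene) +
    sample.int(50000L, n, replace = TRUE)
  ref <- random_bases(n)
  alt <- random_bases(n, exclude = ref)
  source <- rep(c("clinvar", "cosmic"), length.out = n)
  sig <- ifelse(source == "cosmic", "Pathogenic",
                sample(c("Pathogenic", "Likely pathogenic"), n, replace = TRUE))
  # allele-level keys must be unique within source
  tab <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, gene = gene, clinical_significance = sig,
                    source = source, stringsAsFactors = FALSE)
  tab <- tab[!duplicated(paste(tab$source, tab$chrom, tab$pos, tab$ref, tab$alt)), ]
  pathogenicity_catalog(tab)
}

empty_variants <- function() {
  data.frame(sample = character(), cancer_type = character(),
             gene = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(),
             classification = character(), filter = character(),
             origin = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted BRCAness signal
#'
#' Deterministic given the design (which carries the seed): carriers are
#' independent Bernoulli draws at the planted carrier frequency per origin,
#' each carrier receiving one catalog-matching variant; background non-PLP
#' variants (silent and non-silent, mostly PASS) are added per sample. GISTIC
#' codes of -2 are drawn at the planted deletion frequency, other codes from
#' a background distribution. Each gene gets three probes inside the TSS
#' window and one outside. Tumor expression = per-gene baseline + planted
#' shift - silencing coupling x the sample's promoter-beta deviation + noise.
#' Survival is exponential with hazard multiplied per planted gene when the
#' sample's expression exceeds the gene's median, censored uniformly.
#'
#' @param design a [simulation_design()].
#' @return List with `bundle` (a `cohort_bundle`) and `truth` (the planted
#'   design matrices and bookkeeping).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  panel <- design$panel
  types <- design$cancer_types
  genes <- panel$symbol

  tumor_ids <- unlist(lapply(seq_along(types), function(i) {
    sprintf("%s-T%04d", types[i], seq_len(design$n_tumor[i]))
  }))
  normal_ids <- unlist(lapply(seq_along(types), function(i) {
    if (design$n_normal[i] == 0L) return(character())
    sprintf("%s-N%04d", types[i], seq_len(design$n_normal[i]))
  }))
  samples <- data.frame(
    sample = c(tumor_ids, normal_ids),
    cancer_type = c(rep(types, design$n_tumor), rep(types, design$n_normal)),
    sample_type = rep(c("tumor", "normal"),
                      c(length(tumor_ids), length(normal_ids))),
    stringsAsFactors = FALSE
  )
  tumor_type <- samples$cancer_type[match(tumor_ids, samples$sample)]

  catalog <- synthetic_catalog(panel)

  ## --- variants: planted PLP carriers per origin + background noise ------
  var_list <- list(empty_variants())
  for (origin in c("somatic", "germline")) {
    for (g in genes) {
      cat_g <- catalog[catalog$gene == g, , drop = FALSE]
      p <- design$plp_freq[g, tumor_type]
      carrier <- stats::runif(length(tumor_ids)) < p
      if (!any(carrier)) next
      pick <- sample.int(nrow(cat_g), sum(carrier), replace = TRUE)
      var_list[[length(var_list) + 1L]] <- data.frame(
        sample = tumor_ids[carrier], cancer_type = tumor_type[carrier],
        gene = g, chrom = cat_g$chrom[pick], pos = cat_g$pos[pick],
        ref = cat_g$ref[pick], alt = cat_g$alt[pick],
        classification = sample(maf_nonsilent_classes(), sum(carrier),
                                replace = TRUE),
        filter = "PASS", origin = origin, stringsAsFactors = FALSE
      )
    }
  }
  # background variants: off-catalog positions, mixed classifications
  n_bg <- stats::rpois(length(tumor_ids), design$background_mut_rate)
  if (sum(n_bg) > 0) {
    idx <- rep(seq_along(tumor_ids), n_bg)
    gi <- sample.int(nrow(panel), length(idx), replace = TRUE)
    ref <- random_bases(length(idx))
    var_list[[length(var_list) + 1L]] <- data.frame(
      sample = tumor_ids[idx], cancer_type = tumor_type[idx],
      gene = genes[gi], chrom = panel$tss_chrom[gi],
      pos = panel$tss_pos[gi] + 60000L +
        sample.int(40000L, length(idx), replace = TRUE),
      ref = ref, alt = random_bases(length(idx), exclude = ref),
      classification = sample(c(maf_nonsilent_classes(), "Silent", "Intron",
                                "3'UTR"), length(idx), replace = TRUE),
      filter = sample(c("PASS", "artifact"), length(idx), replace = TRUE,
                      prob = c(0.9, 0.1)),
      origin = "somatic", stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, var_list)
  variants <- variants[order(variants$sample, variants$gene, variants$pos), ]
  rownames(variants) <- NULL

  ## --- CNV: GISTIC codes ------------------------------------------------
  nt <- length(tumor_ids)
  cnv <- matrix(0L, nrow(panel), nt, dimnames = list(genes, tumor_ids))
  bg_codes <- c(-1L, 0L, 1L, 2L)
  bg_prob <- c(0.08, 0.84, 0.06, 0.02)
  for (g in genes) {
    homdel <- stats::runif(nt) < design$homdel_freq[g, tumor_type]
    row <- sample(bg_codes, nt, replace = TRUE, prob = bg_prob)
    row[homdel] <- -2L
    cnv[g, ] <- row
  }

  ## --- methylation: 3 in-window probes + 1 outside per gene --------------
  offsets_in <- c(-5000L, 0L, 5000L)
  probes <- data.frame(
    probe = sprintf("cg%07d", seq_len(4L * nrow(panel))),
    gene = rep(genes, each = 4L),
    chrom = rep(panel$tss_chrom, each = 4L),
    pos = rep(panel$tss_pos, each = 4L) + c(offsets_in, 25000L),
    in_window = rep(c(TRUE, TRUE, TRUE, FALSE), nrow(panel)),
    stringsAsFactors = FALSE
  )
  beta <- matrix(NA_real_, nrow(probes), nt,
                 dimnames = list(probes$probe, tumor_ids))
  # per-gene, per-sample promoter deviation shared by the window probes;
  # reused below to couple expression (silencing)
  promoter_dev <- matrix(stats::rnorm(nrow(panel) * nt, sd = 0.1), nrow(panel),
                         nt, dimnames = list(genes, tumor_ids))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    mu <- design$meth_beta[g, tumor_type]
    rows <- which(probes$gene == g)
    for (r in rows) {
      center <- if (probes$in_window[r]) mu + promoter_dev[g, ] else 0.5
      beta[r, ] <- pmin(0.99, pmax(0.01, center +
        stats::rnorm(nt, sd = design$probe_noise_sd)))
    }
  }
  manifest <- probes[, c("probe", "chrom", "pos")]

  ## --- expression: baseline + shift - silencing * promoter deviation -----
  baseline <- stats::runif(nrow(panel), 6, 10)
  names(baseline) <- genes
  all_ids <- c(tumor_ids, normal_ids)
  expr <- matrix(NA_real_, nrow(panel), length(all_ids),
                 dimnames = list(genes, all_ids))
  normal_type <- samples$cancer_type[match(normal_ids, samples$sample)]
  for (g in genes) {
    tum <- baseline[g] + design$expr_shift[g, tumor_type] -
      10 * design$silencing[g, tumor_type] * promoter_dev[g, ] +
      stats::rnorm(nt, sd = design$expr_noise_sd)
    nor <- baseline[g] + stats::rnorm(length(normal_ids),
                                      sd = design$expr_noise_sd)
    expr[g, ] <- pmax(0, c(tum, nor))
  }

  ## --- survival: exponential, rate scaled by planted per-gene hazards ----
  log_rate <- rep(log(design$base_event_rate), nt)
  for (g in genes) {
    hz <- design$hazard[g, tumor_type]
    active <- which(abs(hz - 1) > 1e-12)
    if (!length(active)) next
    med <- tapply(expr[g, tumor_ids], tumor_type, stats::median)
    above <- expr[g, tumor_ids] > med[tumor_type]
    log_rate[active] <- log_rate[active] +
      (above[active] * log(hz[active]))
  }
  t_event <- stats::rexp(nt, rate = exp(log_rate))
  t_cens <- stats::runif(nt, 0, design$censor_max)
  clinical <- data.frame(
    sample = tumor_ids, cancer_type = tumor_type,
    os_days = round(pmin(t_event, t_cens), 2),
    os_event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )

  variants$in_panel <- rep(TRUE, nrow(variants))
  bundle <- list(variants = variants, catalog = catalog, cnv = cnv,
                 methylation = list(beta = beta, manifest = manifest),
                 expression = expr, clinical = clinical, samples = samples,
                 panel = panel)
  class(bundle) <- "cohort_bundle"

  truth <- list(
    plp_freq = design$plp_freq, homdel_freq = design$homdel_freq,
    meth_beta = design$meth_beta, expr_shift = design$expr_shift,
    hazard = design$hazard, silencing = design$silencing,
    reference_types = design$reference_types,
    high_types = attr(design, "high_types"), seed = design$seed
  )
  list(bundle = bundle, truth = truth)
}
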