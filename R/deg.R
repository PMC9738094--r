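# Tumor-vs-normal differential expression: Wilcoxon rank-sum test,
# Benjamini-Hochberg adjustment within each cancer type, fold-change filter.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact null distribution when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with midrank
#' tie correction and continuity correction. When every value in both groups
#' is identical there is no evidence of a shift and p = 1.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return List with `p` (two-sided) and `w` (rank-sum statistic of `x`,
#'   Mann-Whitney form as in [stats::wilcox.test()]).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("rank_sum_test: both groups must be non-empty")
  }
  all_values <- c(x, y)
  if (length(unique(all_values)) == 1L) {
    return(list(p = 1, w = length(x) * length(y) / 2))
  }
  ties <- anyDuplicated(all_values) > 0L
  exact <- !ties && length(all_values) <= 12L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(p = min(1, wt$p.value), w = unname(wt$statistic))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort p ascending, compute p(i) * m / i, enforce monotone non-increase from
#' the largest p downwards, cap at 1, and restore the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes per cancer type
#'
#' Cancer types with fewer than `min_normals` normal samples are skipped
#' entirely (the expression feature is missing for them, not zero). Within
#' each retained type, every panel gene is tested tumor vs normal with
#' [rank_sum_test()]; p-values are BH-adjusted within the type across the
#' panel genes. The fold change defaults to the ratio of linearized means,
#' mean(2^x - 1) tumor over normal (inputs are log2(norm+1));
#' `config$fold_change_scale = "log2"` switches to the difference of log2
#' means (then |diff| >= log2(fold) is required). A gene is a DEG when the
#' adjusted p < `deg_adj_p` and the change is at least `deg_fold_change`
#' (inclusive: exactly two-fold qualifies, in either direction).
#'
#' @param expression gene x sample log2(norm+1) matrix.
#' @param samples sample map (tumor/normal flags).
#' @param panel gene panel.
#' @param config configuration list.
#' @return A `deg_results` list: `results` (gene, cancer_type, n_tumor,
#'   n_normal, fold_change, log2_fc, p, adj_p, is_deg), `counts` (per-type
#'   DEG counts; NA for skipped types) and `skipped` type labels.
#' @export
call_degs <- function(expression, samples, panel, config = default_config()) {
  tumors <- samples$sample[samples$sample_type == "tumor"]
  normals <- samples$sample[samples$sample_type == "normal"]
  types <- sort(unique(samples$cancer_type))
  genes <- intersect(panel$symbol, rownames(expression))
  rows <- list()
  skipped <- character()
  for (t in types) {
    t_ids <- intersect(colnames(expression),
                       intersect(tumors, samples$sample[samples$cancer_type == t]))
    n_ids <- intersect(colnames(expression),
                       intersect(normals, samples$sample[samples$cancer_type == t]))
    if (length(n_ids) < config$min_normals) {
      skipped <- c(skipped, t)
      bn_log("call_degs: %s skipped (%d normal samples < %d)", t,
             length(n_ids), config$min_normals)
      next
    }
    res <- lapply(genes, function(g) {
      tv <- expression[g, t_ids]
      nv <- expression[g, n_ids]
      lin_t <- mean(2^tv - 1)
      lin_n <- mean(2^nv - 1)
      fc <- if (lin_n > 0) lin_t / lin_n else NA_real_
      l2 <- mean(tv) - mean(nv)
      data.frame(gene = g, cancer_type = t, n_tumor = length(t_ids),
                 n_normal = length(n_ids), fold_change = fc, log2_fc = l2,
                 p = rank_sum_test(tv, nv)$p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$adj_p <- bh_adjust(res$p)
    fold <- config$deg_fold_change
    big_change <- if (identical(config$fold_change_scale, "log2")) {
      abs(res$log2_fc) >= log2(fold)
    } else {
      !is.na(res$fold_change) &
        (res$fold_change >= fold | res$fold_change <= 1 / fold)
    }
    res$is_deg <- res$adj_p < config$deg_adj_p & big_change
    rows[[t]] <- res
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  counts <- data.frame(
    cancer_type = types,
    n_deg = vapply(types, function(t) {
      if (t %in% skipped) NA_integer_
      else sum(rows[[t]]$is_deg, na.rm = TRUE)
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- list(results = results, counts = counts, skipped = skipped)
  class(out) <- "deg_results"
  out
}

#' @export
print.deg_results <- function(x, ...) {
  cat(sprintf("<deg_results> %d tested gene-type pairs, %d types skipped\n",
              if (is.null(x$results)) 0L else nrow(x$results),
              length(x$skipped)))
  invisible(x)
}
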