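# Median-split survival screening: Kaplan-Meier curves, two-sided log-rank
# tests, hazard ratios with 95% CIs from the log-rank O/E quantities, the
# per-cancer "risky gene" counts, and 2-group patient stratification on
# panel expression.

#' Split samples into high/low groups at the median expression
#'
#' Values strictly above the median go to "high"; values at or below the
#' median go to "low" (ties at the median go low). When all values are
#' identical, or either group ends up empty, the split is degenerate and is
#' excluded from downstream counts.
#'
#' @param values numeric expression values (>= 2 samples).
#' @param ids optional sample IDs (names of the result).
#' @return List with `group` (factor low/high, named by `ids`) and
#'   `degenerate` flag.
#' @export
median_split <- function(values, ids = names(values)) {
  if (length(values) < 2L) stop("median_split: need at least 2 samples")
  med <- stats::median(values)
  group <- factor(ifelse(values > med, "high", "low"),
                  levels = c("low", "high"))
  if (!is.null(ids)) names(group) <- ids
  degenerate <- length(unique(group)) < 2L
  list(group = group, degenerate = degenerate, median = med)
}

#' Kaplan-Meier survival curve (product-limit estimator)
#'
#' @param times non-negative survival times.
#' @param events event indicators (1 death, 0 censored).
#' @return Data frame time, n_risk, n_event, n_censor, surv -- the
#'   right-continuous step function, starting from S(0) = 1.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop("km_curve: empty input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-sided log-rank test between two groups
#'
#' Standard observed-minus-expected hypergeometric statistic with a
#' chi-square p on 1 degree of freedom. Symmetric in the group labels. With
#' no events at all the statistic is undefined (p = NA).
#'
#' @param times,events survival data for all samples.
#' @param group two-level factor/vector of group labels.
#' @return List: statistic, p, and per-group observed/expected event counts.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0L)) {
    stop("logrank_test: need two non-empty groups")
  }
  if (sum(events) == 0) {
    return(list(statistic = NA_real_, p = NA_real_,
                observed = c(0, 0), expected = c(0, 0),
                levels = levels(group)))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  stat <- sd$chisq
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp),
       levels = levels(group))
}

#' Hazard ratio with 95% CI from log-rank O/E quantities
#'
#' HR = (O1/E1)/(O2/E2) from the log-rank observed/expected event counts,
#' with CI exp(log HR +/- 1.96 sqrt(1/E1 + 1/E2)); group 1 is the
#' `numerator` level. Undefined (all-NA) when either group has zero
#' observed or expected events.
#'
#' @param times,events survival data.
#' @param group two-level group labels.
#' @param numerator group level whose hazard forms the numerator (default
#'   the second factor level, i.e. "high" for a [median_split()] factor).
#' @return List hr, lower, upper (95% CI), defined flag.
#' @export
hazard_ratio <- function(times, events, group, numerator = NULL) {
  group <- factor(group)
  lev <- levels(group)
  numerator <- numerator %||% lev[2L]
  lr <- logrank_test(times, events, group)
  i <- match(numerator, lr$levels)
  j <- setdiff(seq_len(2L), i)
  O1 <- lr$observed[i]; E1 <- lr$expected[i]
  O2 <- lr$observed[j]; E2 <- lr$expected[j]
  if (!is.finite(E1) || !is.finite(E2) || E1 <= 0 || E2 <= 0 ||
      O1 == 0 || O2 == 0) {
    return(list(hr = NA_real_, lower = NA_real_, upper = NA_real_,
                defined = FALSE))
  }
  log_hr <- log((O1 / E1) / (O2 / E2))
  se <- sqrt(1 / E1 + 1 / E2)
  list(hr = exp(log_hr), lower = exp(log_hr - 1.96 * se),
       upper = exp(log_hr + 1.96 * se), defined = TRUE)
}

#' Median-split prognostic screen over the gene panel
#'
#' Per gene per cancer type: split the patients at the gene's median
#' expression, compare overall survival of the high vs low group with a
#' two-sided log-rank test, and report the hazard ratio (high vs low) with
#' its 95% CI -- a forest-table layout. Degenerate splits are skipped and
#' logged. Direction is "risky" when p < `survival_p` and HR > 1,
#' "protective" when p < `survival_p` and HR < 1, "none" otherwise.
#'
#' The per-cancer "risky gene" count defaults to the number of genes with
#' p < `survival_p` in the type (`config$risky_mode = "hr_gt_1"` restricts
#' the count to HR > 1). No multiple-testing adjustment is applied to the
#' survival p-values (raw p < 0.05 screening); treat the counts as a
#' screening feature, not as calibrated discoveries.
#'
#' @param expression gene x sample matrix.
#' @param clinical clinical table (sample, cancer_type, os_days, os_event).
#' @param samples sample map.
#' @param panel gene panel.
#' @param config configuration list.
#' @return A `survival_screen` list: `results` (gene, cancer_type, n_high,
#'   n_low, statistic, p, hr, hr_lower, hr_upper, direction) and
#'   `risky_counts` (cancer_type, n_risky).
#' @export
prognostic_screen <- function(expression, clinical, samples, panel,
                              config = default_config()) {
  genes <- intersect(panel$symbol, rownames(expression))
  types <- sort(unique(clinical$cancer_type))
  rows <- list()
  n_degenerate <- 0L
  for (t in types) {
    clin_t <- clinical[clinical$cancer_type == t, , drop = FALSE]
    ids <- intersect(clin_t$sample, colnames(expression))
    if (length(ids) < 2L) next
    clin_t <- clin_t[match(ids, clin_t$sample), , drop = FALSE]
    for (g in genes) {
      sp <- median_split(expression[g, ids], ids)
      if (sp$degenerate) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      lr <- logrank_test(clin_t$os_days, clin_t$os_event, sp$group)
      hr <- hazard_ratio(clin_t$os_days, clin_t$os_event, sp$group,
                         numerator = "high")
      direction <- if (is.finite(lr$p) && lr$p < config$survival_p &&
                       isTRUE(hr$defined)) {
        if (hr$hr > 1) "risky" else if (hr$hr < 1) "protective" else "none"
      } else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cancer_type = t,
        n_high = sum(sp$group == "high"), n_low = sum(sp$group == "low"),
        statistic = lr$statistic, p = lr$p,
        hr = hr$hr, hr_lower = hr$lower, hr_upper = hr$upper,
        direction = direction, stringsAsFactors = FALSE
      )
    }
  }
  if (n_degenerate > 0L) {
    bn_log("prognostic_screen: skipped %d degenerate median splits",
           n_degenerate)
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  risky_counts <- data.frame(
    cancer_type = types,
    n_risky = vapply(types, function(t) {
      if (is.null(results)) return(0L)
      sub <- results[results$cancer_type == t, , drop = FALSE]
      sig <- is.finite(sub$p) & sub$p < config$survival_p
      if (identical(config$risky_mode, "hr_gt_1")) {
        sig <- sig & is.finite(sub$hr) & sub$hr > 1
      }
      sum(sig)
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- list(results = results, risky_counts = risky_counts)
  class(out) <- "survival_screen"
  out
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("<survival_screen> %d gene-type pairs tested\n",
              if (is.null(x$results)) 0L else nrow(x$results)))
  invisible(x)
}

#' Stratify patients by panel expression (hierarchical clustering)
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of samples
#' on their panel-gene expression profiles, cut at `k` groups. For k = 2 the
#' groups are labeled "lower"/"higher" by their mean panel expression. A
#' simple separation statistic (mean between-group distance over mean
#' within-group distance) is reported; values near 1 indicate no real
#' separation.
#'
#' @param expression gene x sample matrix (panel genes in rows).
#' @param panel gene panel.
#' @param k number of groups (default 2; must be <= number of samples).
#' @return List `groups` (named factor), `sizes`, `separation`.
#' @export
stratify_patients <- function(expression, panel, k = 2L) {
  genes <- intersect(panel$symbol, rownames(expression))
  m <- t(expression[genes, , drop = FALSE])
  if (k > nrow(m)) stop("stratify_patients: k exceeds the number of samples")
  d <- stats::dist(m, method = "euclidean")
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  mean_expr <- tapply(rowMeans(m), cl, mean)
  ord <- order(mean_expr)
  labels <- if (k == 2L) c("lower", "higher") else paste0("group", seq_len(k))
  relabel <- setNames(labels, names(mean_expr)[ord])
  groups <- factor(relabel[as.character(cl)], levels = labels)
  names(groups) <- rownames(m)
  dm <- as.matrix(d)
  same <- outer(cl, cl, "==") & upper.tri(dm)
  diff <- !outer(cl, cl, "==") & upper.tri(dm)
  separation <- if (any(same) && any(diff)) {
    mean(dm[diff]) / mean(dm[same])
  } else NA_real_
  list(groups = groups, sizes = table(groups), separation = separation)
}
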