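#' Default analysis configuration
#'
#' All pipeline thresholds in one place. Defaults:
#' \describe{
#'   \item{beta_threshold}{0.3 -- mean promoter beta above which a gene is
#'     called hypermethylated (strict `>`).}
#'   \item{deg_adj_p}{0.01 -- BH-adjusted p cutoff for a DEG call.}
#'   \item{deg_fold_change}{2 -- minimum fold change (inclusive, linear
#'     scale; `fold_change_scale` switches to log2 differences).}
#'   \item{survival_p}{0.05 -- two-sided log-rank significance level.}
#'   \item{plp_cor_threshold}{0.5 -- |Pearson r| cutoff for pathogenic-variant
#'     frequency correlations.}
#'   \item{homdel_cor_threshold}{0.4 -- |Pearson r| cutoff for
#'     homozygous-deletion frequency correlations.}
#'   \item{tss_window}{10000 -- promoter half-window in bp around the TSS
#'     (boundary inclusive).}
#'   \item{min_normals}{5 -- minimum normal samples for the expression stage
#'     to run in a cancer type.}
#'   \item{meth_assoc_threshold}{0.5 -- |r| cutoff for methylation-expression
#'     silencing/enhancing calls.}
#'   \item{nonsilent_classes}{MAF Variant_Classification values retained by
#'     variant filtering.}
#'   \item{fold_change_scale}{"linear" (ratio of linearized means) or "log2"
#'     (difference of log2 means).}
#'   \item{risky_mode}{"any_significant" (log-rank p < survival_p) or
#'     "hr_gt_1" (additionally hazard ratio > 1).}
#'   \item{qualify_rule}{"sum" (composite Sum > reference Sum) or
#'     "all_columns" (every defined normalized column >= 1).}
#' }
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    beta_threshold = 0.3,
    deg_adj_p = 0.01,
    deg_fold_change = 2,
    survival_p = 0.05,
    plp_cor_threshold = 0.5,
    homdel_cor_threshold = 0.4,
    cor_p = 0.05,
    tss_window = 10000L,
    min_normals = 5L,
    meth_assoc_threshold = 0.5,
    nonsilent_classes = maf_nonsilent_classes(),
    fold_change_scale = "linear",
    risky_mode = "any_significant",
    qualify_rule = "sum"
  )
}

#' Standard MAF non-silent variant classifications
#' @return Character vector of Variant_Classification values.
#' @export
maf_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Splice_Site", "Translation_Start_Site")
}

# silent / non-coding classes recognised but filtered out
maf_silent_classes <- function() {
  c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "RNA",
    "IGR", "Splice_Region", "Targeted_Region")
}

#' Load a configuration file, merging over the defaults
#'
#' @param path YAML key-value file; keys override [default_config()] entries.
#' @return Named configuration list.
#' @export
load_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}

#' Write a configuration list as YAML
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
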