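#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline with the package defaults.
#' Thresholds mirror the published analysis: differentially methylated
#' positions (DMPs) require |Delta-beta| >= 0.35 and a Benjamini-Hochberg
#' adjusted p below 0.01; the cross-cancer common-marker cut is a strict
#' |Delta-beta| > 0.2 in every cancer.
#'
#' @param dmp_abs_dbeta_threshold Absolute Delta-beta needed for a probe to be a
#'   DMP (and, strictly exceeded, for a probe to qualify a primary-marker gene).
#' @param dmp_q_threshold BH-adjusted p threshold for DMP status.
#' @param gene_q_threshold BH-adjusted p threshold in the primary-marker gene
#'   rule.
#' @param common_abs_dbeta_threshold Per-cancer |Delta-beta| cut (strict `>`)
#'   applied to candidate sets before the cross-cancer intersection.
#' @param iqr_k Tukey fence multiplier for per-probe outlier removal; `Inf`
#'   disables filtering.
#' @param min_group_size_after_outliers Minimum samples a group must retain
#'   after outlier removal for the probe to be kept.
#' @param promoter_only If `TRUE` only promoter-region probes can qualify a
#'   gene as a primary marker.
#' @param n_groups Number of functional groups the UPGMA dendrogram is cut
#'   into.
#' @param seed Seed used for the classifier train/test split.
#' @param train_fraction Fraction of subjects per class assigned to training.
#' @param svm_cost Soft-margin cost C of the SVM.
#' @param svm_gamma RBF kernel width; `NULL` means 1 / (n_features * var(X)).
#' @param feature_mode `"probe"` uses each gene's max-|Delta-beta| training
#'   probe as its feature; `"gene_mean"` averages the gene's probes.
#' @return A list of class `"meth_config"`.
#' @export
meth_config <- function(dmp_abs_dbeta_threshold = 0.35,
                        dmp_q_threshold = 0.01,
                        gene_q_threshold = 0.01,
                        common_abs_dbeta_threshold = 0.2,
                        iqr_k = 1.5,
                        min_group_size_after_outliers = 3,
                        promoter_only = TRUE,
                        n_groups = 3,
                        seed = 1L,
                        train_fraction = 0.8,
                        svm_cost = 1,
                        svm_gamma = NULL,
                        feature_mode = c("probe", "gene_mean")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(
    dmp_abs_dbeta_threshold > 0, dmp_q_threshold > 0, gene_q_threshold > 0,
    common_abs_dbeta_threshold > 0, iqr_k >= 0,
    min_group_size_after_outliers >= 1,
    n_groups >= 1, svm_cost > 0,
    train_fraction > 0, train_fraction < 1
  )
  structure(list(
    dmp_abs_dbeta_threshold = dmp_abs_dbeta_threshold,
    dmp_q_threshold = dmp_q_threshold,
    gene_q_threshold = gene_q_threshold,
    common_abs_dbeta_threshold = common_abs_dbeta_threshold,
    iqr_k = iqr_k,
    min_group_size_after_outliers = min_group_size_after_outliers,
    promoter_only = promoter_only,
    n_groups = n_groups,
    seed = as.integer(seed),
    train_fraction = train_fraction,
    svm_cost = svm_cost,
    svm_gamma = svm_gamma,
    feature_mode = feature_mode
  ), class = "meth_config")
}

#' @export
print.meth_config <- function(x, ...) {
  cat("methmark run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-30s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
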