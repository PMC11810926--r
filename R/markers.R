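#' Marker-set container
#'
#' A data.frame of genes with signed delta-beta values, tagged with the
#' cancer it belongs to and its provenance in the pipeline.
#'
#' @param df data.frame with at least columns `gene`, `delta_beta`, `status`.
#' @param cancer Cancer label.
#' @param provenance One of `primary`, `secondary`, `candidate`, `common`.
#' @return The data.frame, class `"marker_set"`.
#' @export
marker_set <- function(df, cancer = NA_character_,
                       provenance = c("primary", "secondary", "candidate",
                                      "common")) {
  provenance <- match.arg(provenance)
  stopifnot(all(c("gene", "delta_beta", "status") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicate genes in marker set")
  rownames(df) <- NULL
  attr(df, "cancer") <- cancer
  attr(df, "provenance") <- provenance
  class(df) <- c("marker_set", "data.frame")
  df
}

#' Union of a cancer's comorbidity gene sets (secondary biomarkers)
#'
#' @param comorbidity_sets Named list of character vectors (one per
#'   comorbidity, as from [read_gene_sets()]).
#' @return Sorted character vector of gene symbols.
#' @export
secondary_markers <- function(comorbidity_sets) {
  stopifnot(length(comorbidity_sets) >= 1)
  sort(unique(toupper(unlist(comorbidity_sets, use.names = FALSE))))
}

#' Candidate biomarkers: primary intersect secondary
#'
#' Keeps the primary markers that also appear in the secondary (comorbidity)
#' union, carrying the primary delta-beta values through.
#'
#' @param primary A primary `marker_set`.
#' @param secondary Character vector of secondary-biomarker gene symbols.
#' @return A candidate `marker_set` (possibly empty).
#' @export
candidate_markers <- function(primary, secondary) {
  stopifnot(inherits(primary, "marker_set"))
  keep <- primary$gene %in% toupper(secondary)
  out <- primary[keep, , drop = FALSE]
  marker_set(as.data.frame(out), cancer = attr(primary, "cancer"),
             provenance = "candidate")
}

#' Cross-cancer common biomarkers
#'
#' A gene is a common biomarker when it appears in every cancer's candidate
#' set with `|delta_beta| > common_abs_dbeta_threshold` (strict) in each.
#' Sign consistency across cancers is not required; hyper/hypo status is
#' reported per cancer.
#'
#' @param candidates Named list of candidate `marker_set`s, one per cancer
#'   (>= 2 cancers).
#' @param config A [meth_config()].
#' @return A data.frame of class `"common_markers"`: one row per gene, one
#'   `delta_beta.<cancer>` and `status.<cancer>` column pair per cancer.
#' @export
common_markers <- function(candidates, config = meth_config()) {
  stopifnot(length(candidates) >= 2)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, attr, "", "cancer")
  }
  thr <- config$common_abs_dbeta_threshold
  per_cancer <- lapply(candidates, function(ms) {
    ms$gene[abs(ms$delta_beta) > thr]
  })
  genes <- sort(Reduce(intersect, per_cancer))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cn in names(candidates)) {
    ms <- candidates[[cn]]
    idx <- match(genes, ms$gene)
    out[[paste0("delta_beta.", cn)]] <- ms$delta_beta[idx]
    out[[paste0("status.", cn)]] <-
      ifelse(ms$delta_beta[idx] > 0, "hyper", "hypo")
  }
  class(out) <- c("common_markers", "data.frame")
  out
}

#' Write a marker set or common-marker table as TSV
#' @param x A `marker_set` or `common_markers` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
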