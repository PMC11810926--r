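#' Run the full biomarker-discovery pipeline on in-memory inputs
#'
#' Wires the stages end to end: per-cancer differential methylation and
#' primary-marker calling; secondary markers from comorbidity gene lists;
#' candidate intersection; cross-cancer common-marker selection; GO
#' functional distance matrix and UPGMA grouping of the common markers;
#' enumeration and SVM evaluation of one-marker-per-group panels; optimal
#' panel selection.
#'
#' @param matrices Named list of `BetaMatrix` objects, one per cancer.
#' @param manifests A single `ProbeManifest` or a named list per cancer.
#' @param comorbidity_sets Named list (per cancer) of named lists of gene
#'   vectors.
#' @param dag A `go_dag` from [read_obo()].
#' @param annotations Annotation data.frame (gene, term).
#' @param config A [meth_config()].
#' @return A list with elements `probe_records`, `primary`, `candidates`,
#'   `common`, `distance_matrix`, `groups`, `panel_reports`, `optimal`.
#' @export
run_pipeline <- function(matrices, manifests, comorbidity_sets, dag,
                         annotations, config = meth_config()) {
  stopifnot(length(matrices) >= 2)
  cancers <- names(matrices)
  one_manifest <- inherits(manifests, "ProbeManifest")
  records <- primary <- candidates <- list()
  for (cn in cancers) {
    mf <- if (one_manifest) manifests else manifests[[cn]]
    rec <- probe_stats(matrices[[cn]], mf, config)
    records[[cn]] <- rec
    primary[[cn]] <- call_primary_markers(rec, config, cancer = cn)
    sec <- secondary_markers(comorbidity_sets[[cn]])
    candidates[[cn]] <- candidate_markers(primary[[cn]], sec)
  }
  common <- common_markers(candidates, config)
  out <- list(probe_records = records, primary = primary,
              candidates = candidates, common = common,
              distance_matrix = NULL, groups = NULL,
              panel_reports = NULL, optimal = NULL)
  if (nrow(common) < 2) {
    warning("fewer than 2 common markers; skipping clustering and panels")
    return(out)
  }
  resource <- build_go_resource(dag, annotations)
  annotated <- common$gene[common$gene %in% names(resource$gene_terms)]
  if (length(annotated) < nrow(common)) {
    warning("dropping unannotated common marker(s): ",
            paste(setdiff(common$gene, annotated), collapse = ", "))
  }
  if (length(annotated) < 2) return(out)
  dmat <- build_gene_distance_matrix(annotated, resource)
  dend <- upgma(dmat)
  k <- min(config$n_groups, length(annotated))
  groups <- cut_groups(dend, k, matrix = dmat)
  reports <- evaluate_panels(matrices, manifests, groups, config)
  out$distance_matrix <- dmat
  out$groups <- groups
  out$panel_reports <- reports
  out$optimal <- select_optimal(reports)
  out
}
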