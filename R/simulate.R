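#' Simulation specification
#'
#' The stated world for all synthetic inputs: cohort sizes, planted
#' differential-methylation effects, the beta noise model, and the outlier
#' mechanism. Beta-values are drawn from Beta distributions parameterized by
#' (mean, precision): `shape1 = mu * phi`, `shape2 = (1 - mu) * phi`, so the
#' per-sample standard deviation is `sqrt(mu (1 - mu) / (1 + phi))`
#' (about 0.05-0.07 at precision 50, the spread of typical post-QC 450K
#' groups). Planted probes shift the tumor mean by the signed effect;
#' effects are validated at spec construction so every mean stays inside
#' (0.02, 0.98) — parameters are constrained, samples are never clipped.
#' Outliers replace a value with a draw near the opposite methylation
#' extreme, the mechanism by which a handful of aberrant subjects can drag a
#' probe's delta-beta below threshold until IQR filtering removes them.
#'
#' @param cancers Character vector of cancer labels.
#' @param n_tumor,n_normal Subjects per group per cancer.
#' @param planted data.frame with columns `gene`, `cancer`, `effect` (signed
#'   delta-beta) and optionally `base_mean` (normal-group mean; default 0.15
#'   for hyper effects, 0.8 for hypo).
#' @param n_null_genes Unaffected genes added per cancer.
#' @param probes_per_gene Probes simulated per gene.
#' @param precision Beta-distribution precision phi.
#' @param outlier_rate Per-cell probability of an outlier replacement.
#' @param promoter_fraction Fraction of null-gene probes placed in promoter
#'   regions (planted probes are always promoter so the primary-marker rule
#'   can see them).
#' @param seed Base seed; recorded in every output.
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(cancers = paste0("cancer", 1:5),
                     n_tumor = 30, n_normal = 30,
                     planted = NULL,
                     n_null_genes = 180,
                     probes_per_gene = 2,
                     precision = 50,
                     outlier_rate = 0.02,
                     promoter_fraction = 0.7,
                     seed = 1L) {
  if (is.null(planted)) {
    planted <- expand.grid(gene = paste0("PLT", 1:20), cancer = cancers,
                           stringsAsFactors = FALSE)
    planted$effect <- 0.4
  }
  stopifnot(all(c("gene", "cancer", "effect") %in% names(planted)))
  if (!"base_mean" %in% names(planted)) {
    planted$base_mean <- ifelse(planted$effect >= 0, 0.15, 0.8)
  }
  stopifnot(all(abs(planted$effect) <= 1))
  tumor_mean <- planted$base_mean + planted$effect
  if (any(planted$base_mean <= 0.02 | planted$base_mean >= 0.98 |
          tumor_mean <= 0.02 | tumor_mean >= 0.98)) {
    stop("planted effect pushes a group mean outside (0.02, 0.98)")
  }
  structure(list(cancers = cancers, n_tumor = n_tumor, n_normal = n_normal,
                 planted = planted, n_null_genes = n_null_genes,
                 probes_per_gene = probes_per_gene, precision = precision,
                 outlier_rate = outlier_rate,
                 promoter_fraction = promoter_fraction,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

rbeta_mp <- function(n, mu, phi) {
  stats::rbeta(n, shape1 = mu * phi, shape2 = (1 - mu) * phi)
}

#' Simulate one cancer's beta-value matrix with planted ground truth
#'
#' Null probes share their group means (drawn from a bimodal-ish mixture of
#' low / intermediate / high methylation, like genome-wide 450K profiles);
#' planted probes add the spec'd effect to the tumor mean. Outliers are
#' injected at the spec rate. Deterministic for a given spec seed + cancer.
#'
#' @param spec A [sim_spec()].
#' @param cancer One of `spec$cancers`.
#' @return List: `beta` (a `BetaMatrix`), `manifest` (`ProbeManifest`),
#'   `truth` (data.frame gene/effect of planted genes in this cancer),
#'   `seed`.
#' @export
simulate_beta_matrix <- function(spec, cancer = spec$cancers[1]) {
  stopifnot(inherits(spec, "sim_spec"), cancer %in% spec$cancers)
  seed <- spec$seed + match(cancer, spec$cancers) * 1000L
  set.seed(seed)
  pl <- spec$planted[spec$planted$cancer == cancer, , drop = FALSE]
  null_genes <- sprintf("NULL%03d", seq_len(spec$n_null_genes))
  genes <- c(pl$gene, null_genes)
  ppg <- spec$probes_per_gene
  manifest <- data.frame(
    probe = sprintf("cg%05d", seq_len(length(genes) * ppg)),
    gene = rep(genes, each = ppg),
    region = "promoter",
    chrom = "chr1",
    pos = seq(0, by = 1000, length.out = length(genes) * ppg),
    stringsAsFactors = FALSE
  )
  is_null <- manifest$gene %in% null_genes
  n_null_probes <- sum(is_null)
  manifest$region[is_null] <-
    ifelse(stats::runif(n_null_probes) < spec$promoter_fraction,
           "promoter", "other")
  # per-probe normal-group means: planted probes use base_mean, null probes
  # a low/mid/high methylation mixture
  mu_normal <- numeric(nrow(manifest))
  mu_normal[!is_null] <- rep(pl$base_mean, each = ppg)
  comp <- sample(1:3, n_null_probes, replace = TRUE, prob = c(.4, .2, .4))
  mu_normal[is_null] <- c(stats::runif(n_null_probes, 0.05, 0.2),
                          stats::runif(n_null_probes, 0.4, 0.6),
                          stats::runif(n_null_probes, 0.8, 0.95)
                          )[(comp - 1) * n_null_probes + seq_len(n_null_probes)]
  mu_tumor <- mu_normal
  mu_tumor[!is_null] <- mu_normal[!is_null] + rep(pl$effect, each = ppg)
  n_t <- spec$n_tumor; n_n <- spec$n_normal
  vals <- base::matrix(NA_real_, nrow(manifest), n_t + n_n)
  rownames(vals) <- manifest$probe
  colnames(vals) <- c(sprintf("%s_T%02d", cancer, seq_len(n_t)),
                      sprintf("%s_N%02d", cancer, seq_len(n_n)))
  for (i in seq_len(nrow(manifest))) {
    vals[i, ] <- c(rbeta_mp(n_t, mu_tumor[i], spec$precision),
                   rbeta_mp(n_n, mu_normal[i], spec$precision))
  }
  if (spec$outlier_rate > 0) {
    out_mask <- stats::runif(length(vals)) < spec$outlier_rate
    flip <- vals[out_mask] >= 0.5
    repl <- numeric(sum(out_mask))
    repl[flip] <- stats::runif(sum(flip), 0, 0.03)
    repl[!flip] <- stats::runif(sum(!flip), 0.97, 1)
    vals[out_mask] <- repl
  }
  groups <- stats::setNames(rep(c("tumor", "normal"), c(n_t, n_n)),
                            colnames(vals))
  list(beta = beta_matrix(vals, groups),
       manifest = probe_manifest(manifest),
       truth = data.frame(gene = pl$gene, effect = pl$effect,
                          stringsAsFactors = FALSE),
       seed = seed)
}

#' Simulate a multi-namespace GO DAG with planted functional groups
#'
#' Builds a three-namespace DAG in which genes of the same planted group
#' share one specific term per namespace (plus a private leaf per gene in
#' biological_process), while genes of different groups share only the
#' namespace roots — so within-group functional distances are small and
#' between-group distances hit the cross-namespace / disjoint-set ceiling.
#' Decoy genes annotated directly to the roots keep root weights at 1.
#' Output is deterministic: the same seed yields byte-identical OBO text.
#'
#' @param groups Named list of character vectors: the planted gene
#'   partition.
#' @param n_decoy_genes Root-annotated background genes.
#' @param seed Seed, recorded in the OBO header.
#' @return List: `obo` (character vector of OBO lines), `annotations`
#'   (data.frame gene/term), `truth` (named membership vector), `seed`.
#' @export
simulate_go <- function(groups, n_decoy_genes = 10, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups))) names(groups) <- paste0("grp", seq_along(groups))
  ns <- c(bp = "biological_process", cc = "cellular_component",
          mf = "molecular_function")
  lines <- c("format-version: 1.2",
             sprintf("! synthetic ontology, seed %d", seed), "")
  ann_gene <- character(); ann_term <- character()
  term_idx <- 0L
  new_id <- function() {
    term_idx <<- term_idx + 1L
    sprintf("GO:%07d", term_idx)
  }
  stanza <- function(id, name, nspace, parents = character()) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      paste0("namespace: ", nspace),
      if (length(parents)) paste0("is_a: ", parents), "")
  }
  roots <- character()
  for (k in names(ns)) {
    root <- new_id()
    roots[k] <- root
    lines <- c(lines, stanza(root, paste0(k, "_root"), ns[[k]]))
    for (gname in names(groups)) {
      gterm <- new_id()
      lines <- c(lines,
                 stanza(gterm, paste(k, gname, "shared"), ns[[k]], root))
      for (gene in groups[[gname]]) {
        ann_gene <- c(ann_gene, gene); ann_term <- c(ann_term, gterm)
        if (k == "bp") {   # private leaf per gene for annotation depth
          pterm <- new_id()
          lines <- c(lines,
                     stanza(pterm, paste("bp private", gene), ns[[k]], gterm))
          ann_gene <- c(ann_gene, gene); ann_term <- c(ann_term, pterm)
        }
      }
    }
  }
  decoys <- sprintf("BG%03d", seq_len(n_decoy_genes))
  for (d in decoys) {
    for (k in names(ns)) {
      ann_gene <- c(ann_gene, d); ann_term <- c(ann_term, roots[k])
    }
  }
  truth <- stats::setNames(rep(names(groups), lengths(groups)),
                           unlist(groups, use.names = FALSE))
  list(obo = lines,
       annotations = data.frame(gene = ann_gene, term = ann_term,
                                stringsAsFactors = FALSE),
       truth = truth, seed = as.integer(seed))
}

#' Simulate comorbidity gene lists covering planted markers
#'
#' Each cancer gets comorbidity gene sets that contain its planted marker
#' genes at the stated coverage plus decoy genes, emulating gene-disease
#' database exports.
#'
#' @param spec A [sim_spec()].
#' @param coverage Fraction of planted genes included (default 1).
#' @param n_decoys Decoy genes per cancer.
#' @param n_comorbidities Lists the genes are split across, per cancer.
#' @return Named list (per cancer) of named lists of gene vectors.
#' @export
simulate_comorbidity_sets <- function(spec, coverage = 1, n_decoys = 30,
                                      n_comorbidities = 2) {
  stopifnot(inherits(spec, "sim_spec"), coverage >= 0, coverage <= 1)
  set.seed(spec$seed + 777L)
  out <- lapply(spec$cancers, function(cn) {
    planted <- unique(spec$planted$gene[spec$planted$cancer == cn])
    n_keep <- round(coverage * length(planted))
    kept <- if (n_keep > 0) sort(sample(planted, n_keep)) else character()
    decoys <- sprintf("CMB_%s_%03d", toupper(cn), seq_len(n_decoys))
    pool <- c(kept, decoys)
    idx <- rep_len(seq_len(n_comorbidities), length(pool))
    sets <- split(pool, idx)
    names(sets) <- sprintf("%s_comorbidity%d", cn,
                           seq_len(length(sets)))
    sets
  })
  stats::setNames(out, spec$cancers)
}

#' Write simulated inputs to a directory in the package's file formats
#'
#' Emits, per cancer, the beta matrix + labels + manifest TSVs, the
#' comorbidity gene lists, and the shared OBO + annotation files — exactly
#' what the readers in this package consume.
#'
#' @param spec A [sim_spec()].
#' @param go A [simulate_go()] result.
#' @param dir Output directory (created if needed).
#' @param coverage Passed to [simulate_comorbidity_sets()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(spec, go, dir, coverage = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in spec$cancers) {
    sim <- simulate_beta_matrix(spec, cn)
    write_beta_matrix(sim$beta, file.path(dir, paste0(cn, "_beta.tsv")),
                      file.path(dir, paste0(cn, "_labels.tsv")))
    utils::write.table(sim$manifest,
                       file.path(dir, paste0(cn, "_manifest.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  com <- simulate_comorbidity_sets(spec, coverage = coverage)
  for (cn in names(com)) {
    for (nm in names(com[[cn]])) {
      writeLines(com[[cn]][[nm]], file.path(dir, paste0(nm, ".txt")))
    }
  }
  writeLines(go$obo, file.path(dir, "ontology.obo"))
  utils::write.table(go$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}
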