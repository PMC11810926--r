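#' Build a GO resource: propagated annotations, weights, ancestor sets
#'
#' Applies the true-path rule: a gene annotated to a term is implicitly
#' annotated to every ancestor of that term (following `is_a` edges up to the
#' namespace root). The propagated term gene sets drive the term weight
#' W(t) = |G_t| / (number of non-duplicate annotated genes), the quantity on
#' which the information-content distance is built. Propagation guarantees
#' W(ancestor) >= W(descendant), hence a non-negative IC distance.
#'
#' @param dag A [read_obo()] result (`go_dag`).
#' @param annotations data.frame with columns `gene`, `term` (direct
#'   annotations); unknown terms are skipped with a warning.
#' @return An object of class `"GoResource"`: `dag`, `term_genes` (list of
#'   propagated gene sets), `weights` (named numeric), `ancestors` (list of
#'   ancestor term ids, each term its own ancestor), `gene_terms` (direct
#'   annotations per gene), `total_genes`.
#' @export
build_go_resource <- function(dag, annotations) {
  stopifnot(inherits(dag, "go_dag"))
  g <- dag_graph(dag)
  if (!igraph::is_dag(g)) stop("is_a graph contains a cycle")
  ids <- dag$terms$id
  unknown <- !(annotations$term %in% ids)
  if (any(unknown)) {
    warning("skipping annotation(s) to unknown term(s): ",
            paste(unique(annotations$term[unknown]), collapse = ", "))
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  term_genes <- stats::setNames(
    lapply(ids, function(t) unique(annotations$gene[annotations$term == t])),
    ids)
  # children first: edges run child -> parent, so "out" topological order
  # lists a child before any of its ancestors
  topo <- names(igraph::topo_sort(g, mode = "out"))
  adj <- igraph::adjacent_vertices(g, topo, mode = "out")
  for (i in seq_along(topo)) {
    child <- topo[i]
    for (parent in names(adj[[i]])) {
      term_genes[[parent]] <- union(term_genes[[parent]], term_genes[[child]])
    }
  }
  term_genes <- lapply(term_genes, sort)
  all_genes <- sort(unique(annotations$gene))
  total <- length(all_genes)
  if (total == 0) stop("no annotated genes")
  weights <- vapply(term_genes, length, 0L) / total
  anc <- lapply(ids, function(t) {
    names(igraph::subcomponent(g, t, mode = "out"))
  })
  names(anc) <- ids
  gene_terms <- split(annotations$term, annotations$gene)
  structure(list(dag = dag, term_genes = term_genes, weights = weights,
                 ancestors = anc, gene_terms = gene_terms,
                 total_genes = total),
            class = "GoResource")
}

#' @export
print.GoResource <- function(x, ...) {
  cat(sprintf("GoResource: %d terms, %d annotated genes\n",
              nrow(x$dag$terms), x$total_genes))
  invisible(x)
}

#' Term weight W(t)
#'
#' Fraction of all non-duplicate annotated genes carried by term `t` after
#' true-path propagation. Root terms of a fully annotated namespace have
#' weight 1; deeper (more specific) terms have lower weights. A term with an
#' empty propagated set gets weight 0 (flagged via attribute).
#'
#' @param t Term id.
#' @param resource A `GoResource`.
#' @return Weight in \[0, 1\].
#' @export
term_weight <- function(t, resource) {
  stopifnot(inherits(resource, "GoResource"))
  if (!t %in% names(resource$weights)) stop("unknown term: ", t)
  w <- unname(resource$weights[[t]])
  if (w == 0) attr(w, "flagged") <- "empty propagated gene set"
  w
}

#' Weight of the lowest common ancestor of two terms
#'
#' Every term is an ancestor of itself. Among all common ancestors the
#' minimum-weight one is taken — the most specific shared term, since weights
#' grow toward the namespace root. Terms in different namespaces share no
#' ancestor and yield `NA`.
#'
#' @param ti,tj Term ids.
#' @param resource A `GoResource`.
#' @return The LCA weight, or `NA_real_` if no common ancestor exists.
#' @export
lca_weight <- function(ti, tj, resource) {
  stopifnot(inherits(resource, "GoResource"))
  common <- intersect(resource$ancestors[[ti]], resource$ancestors[[tj]])
  if (length(common) == 0) return(NA_real_)
  min(resource$weights[common])
}

#' Information-content distance between two GO terms
#'
#' `2 * W(LCA) - W(ti) - W(tj)` when a common ancestor exists; exactly 1
#' when the terms live in different namespaces (no common ancestor). Under
#' true-path propagation the result is always non-negative, and can exceed 1
#' (e.g. siblings directly under a weight-1 root), which is why the final
#' gene distance matrix is normalized.
#'
#' @inheritParams lca_weight
#' @return Non-negative numeric.
#' @export
dist_ic <- function(ti, tj, resource) {
  w_lca <- lca_weight(ti, tj, resource)
  if (is.na(w_lca)) return(1)
  2 * w_lca - unname(resource$weights[[ti]]) - unname(resource$weights[[tj]])
}

#' Sorensen-Dice distance between two terms' gene sets
#'
#' `|G_ti symmetric-difference G_tj| / (|G_ti union G_tj| + |G_ti intersect
#' G_tj|)`: 0 for identical sets, 1 for disjoint ones.
#'
#' @inheritParams lca_weight
#' @return Numeric in \[0, 1\].
#' @export
dist_sc <- function(ti, tj, resource) {
  stopifnot(inherits(resource, "GoResource"))
  gi <- resource$term_genes[[ti]]
  gj <- resource$term_genes[[tj]]
  if (length(gi) == 0 && length(gj) == 0) {
    stop("both terms have empty gene sets: ", ti, ", ", tj)
  }
  n_int <- length(intersect(gi, gj))
  n_uni <- length(union(gi, gj))
  (n_uni - n_int) / (n_uni + n_int)
}

#' Combined term distance
#'
#' Arithmetic mean of the information-content and Sorensen-Dice components.
#'
#' @inheritParams lca_weight
#' @return Numeric.
#' @export
term_distance <- function(ti, tj, resource) {
  (dist_ic(ti, tj, resource) + dist_sc(ti, tj, resource)) / 2
}

#' Functional distance between two genes
#'
#' Mean of [term_distance()] over the full cross-product of the genes'
#' directly annotated terms. `gene_distance(a, a)` is 0 by convention
#' (matrix diagonal). Two genes annotated only to different-namespace terms
#' with disjoint gene sets are at distance exactly 1.
#'
#' @param a,b Gene symbols.
#' @param resource A `GoResource`.
#' @return Numeric.
#' @export
gene_distance <- function(a, b, resource) {
  stopifnot(inherits(resource, "GoResource"))
  if (a == b) return(0)
  ta <- resource$gene_terms[[a]]
  tb <- resource$gene_terms[[b]]
  if (is.null(ta) || length(ta) == 0) stop("gene has no annotations: ", a)
  if (is.null(tb) || length(tb) == 0) stop("gene has no annotations: ", b)
  acc <- 0
  for (ti in ta) for (tj in tb) acc <- acc + term_distance(ti, tj, resource)
  acc / (length(ta) * length(tb))
}

#' Normalized gene functional distance matrix
#'
#' Symmetric matrix of [gene_distance()] values with a zero diagonal. When
#' the raw maximum off-diagonal entry exceeds 1 (possible because the IC
#' component can exceed 1), all off-diagonal entries are divided by that
#' maximum so the matrix lies in \[0, 1\]; otherwise values are left
#' untouched, preserving the analytic anchor that a cross-namespace
#' disjoint-set pair sits at exactly 1.
#'
#' @param genes Character vector of gene symbols (>= 2).
#' @param resource A `GoResource`.
#' @return A `"GeneDistanceMatrix"`: numeric matrix with attribute
#'   `norm_factor` (the divisor applied; 1 when none was needed).
#' @export
build_gene_distance_matrix <- function(genes, resource) {
  stopifnot(length(genes) >= 2)
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- gene_distance(genes[i], genes[j], resource)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  norm <- max(m[upper.tri(m)], 0)
  if (norm > 1) {
    off <- row(m) != col(m)
    m[off] <- m[off] / norm
  } else {
    norm <- 1
  }
  attr(m, "norm_factor") <- norm
  class(m) <- c("GeneDistanceMatrix", class(m))
  m
}

#' Write a gene distance matrix as TSV
#' @param m A `GeneDistanceMatrix` (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
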