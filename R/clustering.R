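#' UPGMA hierarchical clustering of a gene distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters, the distance from a merged cluster to
#' any other being the size-weighted mean of its members' distances. Ties at
#' the minimum are broken deterministically by the lexicographically
#' smallest member label (then the smallest label of the partner cluster),
#' so the dendrogram is invariant to input ordering.
#'
#' @param matrix Symmetric distance matrix with gene row/col names
#'   (a `GeneDistanceMatrix` or plain matrix), >= 2 genes.
#' @return An object of class `"hclust"` (merge, height, order, labels),
#'   usable with [stats::cutree()], [ape::as.phylo()], etc.
#' @export
upgma <- function(matrix) {
  m <- unclass(matrix)
  attr(m, "norm_factor") <- NULL
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("g", seq_len(n))
  if (n < 2) stop("need at least 2 genes to cluster")
  stopifnot(isTRUE(all.equal(m, t(m))))
  labels <- rownames(m)
  # active clusters: id < 0 = singleton -i, id > 0 = merge row
  active <- as.list(-seq_len(n))
  members <- as.list(seq_len(n))          # row indices of original matrix
  minlab <- labels                         # lexicographic tie-break key
  sizes <- rep(1L, n)
  d <- m
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        a <- idx[ii]; b <- idx[jj]
        dist_ab <- d[a, b]
        key <- sort(c(minlab[a], minlab[b]))
        cand <- list(a = a, b = b, d = dist_ab, key = key)
        if (is.null(best) || dist_ab < best$d - 1e-12 ||
            (abs(dist_ab - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(active[[a]], active[[b]]))
    height[step] <- best$d
    # UPGMA update: size-weighted average distance to every other cluster
    for (o in which(alive)) {
      if (o == a || o == b) next
      d[a, o] <- d[o, a] <-
        (sizes[a] * d[a, o] + sizes[b] * d[b, o]) / (sizes[a] + sizes[b])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    minlab[a] <- min(minlab[a], minlab[b])
    active[[a]] <- step
    alive[b] <- FALSE
  }
  hc <- list(merge = merge, height = height,
             order = hclust_order(merge),
             labels = labels, method = "upgma",
             call = match.call(), dist.method = "gene functional distance")
  class(hc) <- "hclust"
  hc
}

# leaf order by recursive traversal of the merge table
hclust_order <- function(merge) {
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  rec(nrow(merge))
}

#' Cut a dendrogram into k functional groups
#'
#' Cuts at the k-1 highest merges. Groups are labeled by their
#' lexicographically smallest member; when a distance matrix is supplied a
#' medoid representative is attached per group.
#'
#' @param dendrogram An `"hclust"` object from [upgma()].
#' @param k Number of groups, `1 <= k <= n`.
#' @param matrix Optional distance matrix for [pick_representative()].
#' @return A list of class `"functional_groups"`: `groups` (named list of
#'   gene vectors), `membership` (named integer), `k`, `dendrogram`,
#'   `representatives` (named character, or `NULL` without a matrix).
#' @export
cut_groups <- function(dendrogram, k, matrix = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  memb <- stats::cutree(dendrogram, k = k)
  groups <- split(names(memb), memb)
  names(groups) <- vapply(groups, min, "")
  groups <- groups[order(names(groups))]
  memb_out <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                              unlist(groups, use.names = FALSE))
  memb_out <- memb_out[dendrogram$labels]
  reps <- NULL
  if (!is.null(matrix)) {
    reps <- vapply(groups, pick_representative, "", matrix = matrix)
  }
  structure(list(groups = groups, membership = memb_out, k = k,
                 dendrogram = dendrogram, representatives = reps),
            class = "functional_groups")
}

#' @export
print.functional_groups <- function(x, ...) {
  cat(sprintf("%d functional group(s):\n", x$k))
  for (i in seq_along(x$groups)) {
    rep_tag <- if (!is.null(x$representatives)) {
      sprintf(" [rep: %s]", x$representatives[[i]])
    } else ""
    cat(sprintf("  %s: %s%s\n", names(x$groups)[i],
                paste(x$groups[[i]], collapse = ", "), rep_tag))
  }
  invisible(x)
}

#' Medoid representative of a functional group
#'
#' The gene minimizing the summed within-group distance; singletons return
#' themselves; ties resolve lexicographically.
#'
#' @param group Character vector of gene symbols (non-empty).
#' @param matrix Distance matrix containing the group's genes.
#' @return A single gene symbol.
#' @export
pick_representative <- function(group, matrix) {
  stopifnot(length(group) >= 1)
  if (length(group) == 1) return(group)
  sub <- unclass(matrix)[group, group, drop = FALSE]
  sums <- rowSums(sub)
  group[order(sums, group)][1]
}

#' Export a dendrogram in Newick format
#' @param dendrogram An `"hclust"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export functional groups as TSV (gene, group id, representative flag)
#' @param groups A `"functional_groups"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  gene <- unlist(groups$groups, use.names = FALSE)
  gid <- rep(names(groups$groups), lengths(groups$groups))
  rep_flag <- if (!is.null(groups$representatives)) {
    gene %in% groups$representatives
  } else NA
  utils::write.table(data.frame(gene = gene, group = gid,
                                representative = rep_flag),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
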