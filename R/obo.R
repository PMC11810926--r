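#' Read a Gene Ontology DAG from OBO text
#'
#' Parses the OBO 1.2 subset used here: `[Term]` stanzas with `id`, `name`,
#' `namespace` and `is_a` lines. Obsolete terms are skipped. The `is_a`
#' relation must be acyclic (it is a DAG by definition); a cycle is a hard
#' error. Other relationship types (e.g. part_of) are ignored.
#'
#' @param path Path to the OBO file.
#' @return A list of class `"go_dag"` with `terms` (data.frame: id, name,
#'   namespace) and `edges` (data.frame: child, parent).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  edges_child <- character()
  edges_parent <- character()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  in_term <- FALSE
  for (ln in c(lines, "[Term]")) {   # sentinel flushes the last stanza
    ln <- trimws(ln)
    if (ln == "[Term]" || grepl("^\\[", ln)) {
      rec <- flush(if (in_term) cur else NULL)
      if (!is.null(rec)) {
        terms[[length(terms) + 1]] <- rec[c("id", "name", "namespace")]
        for (p in rec$parents) {
          edges_child <- c(edges_child, rec$id)
          edges_parent <- c(edges_parent, p)
        }
      }
      in_term <- ln == "[Term]"
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  parents = character(), obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  if (length(terms) == 0) stop("no terms in OBO file: ", path)
  tdf <- data.frame(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, `[[`, "", "name"),
    namespace = vapply(terms, `[[`, "", "namespace"),
    stringsAsFactors = FALSE
  )
  valid_ns <- c("biological_process", "cellular_component",
                "molecular_function")
  if (!all(tdf$namespace %in% valid_ns)) {
    stop("unknown namespace: ",
         paste(setdiff(tdf$namespace, valid_ns), collapse = ", "))
  }
  keep <- edges_parent %in% tdf$id & edges_child %in% tdf$id
  edf <- data.frame(child = edges_child[keep], parent = edges_parent[keep],
                    stringsAsFactors = FALSE)
  dag <- structure(list(terms = tdf, edges = edf), class = "go_dag")
  g <- dag_graph(dag)
  if (!igraph::is_dag(g)) stop("is_a graph contains a cycle")
  dag
}

dag_graph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                vertices = dag$terms$id)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms, %d is_a edges, namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(sort(unique(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

#' Read gene -> GO term annotations
#'
#' Two-column delimited text (gene, term). Annotations to terms absent from
#' the DAG are skipped with a warning when a DAG is supplied.
#'
#' @param path Path to the annotation table.
#' @param dag Optional `go_dag` for term validation.
#' @param sep Field separator.
#' @return data.frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path, dag = NULL, sep = "\t") {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  a <- utils::read.table(path, header = FALSE, sep = sep,
                         stringsAsFactors = FALSE,
                         col.names = c("gene", "term"))
  a$gene <- toupper(a$gene)
  a <- unique(a)
  if (!is.null(dag)) {
    unknown <- !(a$term %in% dag$terms$id)
    if (any(unknown)) {
      warning("skipping annotation(s) to unknown term(s): ",
              paste(unique(a$term[unknown]), collapse = ", "))
      a <- a[!unknown, , drop = FALSE]
    }
  }
  rownames(a) <- NULL
  a
}
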