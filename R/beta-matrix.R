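#' Beta-value matrix with tumor/normal group labels
#'
#' Container for a probes x samples matrix of methylation beta-values in
#' \[0, 1\] (missing values allowed) plus a sample -> group mapping.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups Named character vector mapping every sample id to
#'   `"tumor"` or `"normal"`.
#' @return An object of class `"BetaMatrix"` with elements `values` and
#'   `groups`.
#' @export
beta_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  groups <- groups[colnames(values)]
  if (anyNA(names(groups)) || length(groups) != ncol(values)) {
    missing <- setdiff(colnames(values), names(groups))
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "))
  }
  if (!all(groups %in% c("tumor", "normal"))) {
    stop("group labels must be 'tumor' or 'normal'")
  }
  if (!all(c("tumor", "normal") %in% groups)) {
    stop("need at least one sample in each group")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta-value outside [0,1] at probe '%s', sample '%s' (%g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]))
  }
  structure(list(values = values, groups = groups), class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  invisible(x)
}

#' Samples of one group
#' @param x A `BetaMatrix`.
#' @param group `"tumor"` or `"normal"`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "BetaMatrix"))
  names(x$groups)[x$groups == group]
}

#' Read a beta-value matrix from delimited text
#'
#' The matrix file has a header of sample ids and probe ids in the first
#' column; the label file has two columns (sample, group). Values must lie in
#' \[0, 1\]; out-of-range values are an error, never clamped. Probes whose
#' values are all missing are dropped with a warning.
#'
#' @param path Path to the TSV/CSV matrix.
#' @param labels_path Path to the two-column sample/group table, or a named
#'   character vector of groups.
#' @param sep Field separator (default tab).
#' @return A [beta_matrix()] object.
#' @export
read_beta_matrix <- function(path, labels_path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(raw)
  storage.mode(values) <- "double"
  all_missing <- rowSums(!is.na(values)) == 0
  if (any(all_missing)) {
    warning("dropping probe(s) with all-missing values: ",
            paste(rownames(values)[all_missing], collapse = ", "))
    values <- values[!all_missing, , drop = FALSE]
  }
  if (is.character(labels_path)) {
    if (length(labels_path) == 1 && file.exists(labels_path)) {
      lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                               stringsAsFactors = FALSE)
      groups <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
    } else if (!is.null(names(labels_path))) {
      groups <- labels_path
    } else {
      stop("no such label file: ", labels_path)
    }
  } else {
    stop("labels_path must be a file path or a named character vector")
  }
  beta_matrix(values, groups)
}

#' Write a beta-value matrix (and its labels) to delimited text
#'
#' Values are written at full precision so a write/read round trip is
#' bit-exact.
#'
#' @param x A `BetaMatrix`.
#' @param path Output path for the matrix.
#' @param labels_path Optional output path for the sample/group table.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, labels_path = NULL, sep = "\t") {
  stopifnot(inherits(x, "BetaMatrix"))
  df <- data.frame(probe = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(data.frame(names(x$groups), unname(x$groups)),
                       labels_path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a probe manifest
#'
#' Maps probes to gene symbol, region category (`promoter` / `other`),
#' chromosome and 0-based position. Positions are informational only.
#'
#' @param path Delimited file with columns probe, gene, region, chrom, pos.
#' @param sep Field separator.
#' @return A data.frame of class `"ProbeManifest"`.
#' @export
read_manifest <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  probe_manifest(m)
}

#' Construct/validate a probe manifest
#' @param df Data frame with columns `probe`, `gene`, `region` and optionally
#'   `chrom`, `pos` (0-based).
#' @return The validated data.frame, class `"ProbeManifest"`.
#' @export
probe_manifest <- function(df) {
  need <- c("probe", "gene", "region")
  if (!all(need %in% names(df))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$probe)) stop("manifest maps a probe to multiple genes")
  if (!all(df$region %in% c("promoter", "other"))) {
    stop("region must be 'promoter' or 'other'")
  }
  class(df) <- c("ProbeManifest", "data.frame")
  df
}

#' Read per-comorbidity gene lists
#'
#' One gene symbol per line; symbols are upper-cased and deduplicated.
#' An empty file yields an empty set with a warning.
#'
#' @param paths Named character vector of file paths; names are comorbidity
#'   labels (defaults to file base names).
#' @return Named list of character vectors (gene sets).
#' @export
read_gene_sets <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (!file.exists(p)) stop("no such gene-list file: ", p)
    lines <- readLines(p, warn = FALSE)
    genes <- toupper(trimws(lines))
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0) {
      warning("empty gene list: ", p)
    }
    genes
  })
  stats::setNames(out, names(paths))
}
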