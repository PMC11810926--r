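# Shared fixtures and independent oracles.

# small deterministic beta matrix: 3 probes x 4 samples
make_toy_beta <- function(values = 0.5) {
  v <- matrix(values, 3, 4,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  beta_matrix(v, c(s1 = "tumor", s2 = "tumor", s3 = "normal", s4 = "normal"))
}

make_toy_manifest <- function(probes = paste0("p", 1:3),
                              genes = c("GA", "GA", "GB"),
                              region = c("promoter", "other", "promoter")) {
  probe_manifest(data.frame(probe = probes, gene = genes, region = region,
                            chrom = "chr1", pos = seq_along(probes) - 1,
                            stringsAsFactors = FALSE))
}

# write OBO lines to a temp file and read them back through the package
read_obo_lines <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  on.exit(unlink(path))
  read_obo(path)
}

obo_term <- function(id, ns, parents = character()) {
  c("[Term]", paste0("id: ", id), paste0("name: ", id),
    paste0("namespace: ", ns),
    if (length(parents)) paste0("is_a: ", parents), "")
}

# root (all 10 genes) + two sibling leaves (1 gene each): raw IC distance
# between the leaves is 2*1 - 0.1 - 0.1 = 1.8
make_sibling_resource <- function() {
  lines <- c("format-version: 1.2", "",
             obo_term("GO:0000001", "biological_process"),
             obo_term("GO:0000002", "biological_process", "GO:0000001"),
             obo_term("GO:0000003", "biological_process", "GO:0000001"))
  dag <- read_obo_lines(lines)
  ann <- data.frame(
    gene = c("GENE1", "GENE2", paste0("BG", 1:8)),
    term = c("GO:0000002", "GO:0000003", rep("GO:0000001", 8)),
    stringsAsFactors = FALSE)
  build_go_resource(dag, ann)
}

# two namespaces, one annotated term each, disjoint gene sets
make_cross_ns_resource <- function() {
  lines <- c("format-version: 1.2", "",
             obo_term("GO:0000001", "biological_process"),
             obo_term("GO:0000002", "molecular_function"))
  dag <- read_obo_lines(lines)
  ann <- data.frame(gene = c("GENEA", "GENEB"),
                    term = c("GO:0000001", "GO:0000002"),
                    stringsAsFactors = FALSE)
  build_go_resource(dag, ann)
}

# --- independent oracles -------------------------------------------------

# BH step-up, written as the textbook scan (independent of bh_adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}

# exhaustive ancestor enumeration straight off the edge list
ancestors_oracle <- function(term, edges) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(edges$parent[edges$child %in% frontier], seen)
  }
  seen
}

lca_weight_oracle <- function(ti, tj, resource) {
  edges <- resource$dag$edges
  common <- intersect(ancestors_oracle(ti, edges),
                      ancestors_oracle(tj, edges))
  if (length(common) == 0) return(NA_real_)
  min(resource$weights[common])
}

# random layered DAG with random annotations, for property tests
random_go_resource <- function(n_terms, n_genes = 8, namespaces = 1) {
  ns_names <- c("biological_process", "cellular_component",
                "molecular_function")[seq_len(namespaces)]
  ns_of <- sort(rep_len(seq_len(namespaces), n_terms))
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n_terms)) {
    earlier <- which(ns_of[seq_len(i - 1)] == ns_of[i])
    parents <- if (length(earlier)) {
      ids[sample(earlier, min(length(earlier), sample(1:2, 1)))]
    } else character()
    lines <- c(lines, obo_term(ids[i], ns_names[ns_of[i]], parents))
  }
  dag <- read_obo_lines(lines)
  genes <- sprintf("G%03d", seq_len(n_genes))
  ann <- data.frame(gene = sample(genes, n_terms * 2, replace = TRUE),
                    term = sample(ids, n_terms * 2, replace = TRUE),
                    stringsAsFactors = FALSE)
  build_go_resource(dag, unique(ann))
}

# beta matrix realizing the outlier-flip scenario: a few near-zero tumor
# outliers drag delta-beta below 0.35; IQR filtering restores ~0.40
make_outlier_flip_matrix <- function() {
  jit_t <- seq(-13, 12) * 1e-4
  jit_n <- seq(-14.5, 14.5) * 1e-4
  tumor <- c(0.50 + jit_t - mean(jit_t), rep(0.02, 4))
  normal <- 0.10 + jit_n - mean(jit_n)
  null_t <- 0.30 + jit_n - mean(jit_n)
  null_n <- 0.30 + rev(jit_n) - mean(jit_n)
  v <- rbind(flip = c(tumor, normal), null = c(null_t, null_n))
  colnames(v) <- c(sprintf("t%02d", 1:30), sprintf("n%02d", 1:30))
  groups <- stats::setNames(rep(c("tumor", "normal"), each = 30),
                            colnames(v))
  beta_matrix(v, groups)
}

make_flip_manifest <- function() {
  probe_manifest(data.frame(probe = c("flip", "null"),
                            gene = c("MARK1", "MARK2"),
                            region = "promoter", chrom = "chr1", pos = 0:1,
                            stringsAsFactors = FALSE))
}
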