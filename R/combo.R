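#' Enumerate one-marker-per-group panels
#'
#' Cartesian product over functional groups: every combination takes exactly
#' one gene from each group, so the number of panels is the product of the
#' group sizes.
#'
#' @param groups A `"functional_groups"` object (or named list of gene
#'   vectors), every group non-empty.
#' @return List of character vectors (panels), genes in group order.
#' @export
enumerate_panels <- function(groups) {
  gs <- if (inherits(groups, "functional_groups")) groups$groups else groups
  stopifnot(length(gs) >= 1, all(lengths(gs) >= 1))
  grid <- expand.grid(gs, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  panels <- lapply(seq_len(nrow(grid)), function(i) {
    unname(unlist(grid[i, ], use.names = FALSE))
  })
  panels
}

#' Build a per-subject feature table for a marker panel
#'
#' One feature per panel gene. In `"probe"` mode (default) the feature is
#' the beta-value of the gene's representative probe — the probe with the
#' largest |delta-beta| computed on the training subjects only, so the
#' column definition carries over unchanged to held-out data. In
#' `"gene_mean"` mode the feature is the mean beta across the gene's
#' probes. Missing values are imputed with the training-set feature median.
#'
#' @param matrix A `BetaMatrix` covering all subjects.
#' @param manifest A `ProbeManifest`.
#' @param panel Character vector of panel genes; a gene with no probe in the
#'   matrix is an error.
#' @param train_samples Sample ids used to choose probes and imputation
#'   statistics (defaults to all samples).
#' @param feature_mode `"probe"` or `"gene_mean"`.
#' @param cancer Optional cancer-of-origin label stored on the table.
#' @return A list of class `"feature_table"`: `x` (subjects x genes), `y`
#'   (character labels), `probes` (chosen probe per gene, `NA` in gene-mean
#'   mode), `cancer`.
#' @export
extract_features <- function(matrix, manifest, panel,
                             train_samples = colnames(matrix$values),
                             feature_mode = c("probe", "gene_mean"),
                             cancer = NA_character_) {
  stopifnot(inherits(matrix, "BetaMatrix"))
  feature_mode <- match.arg(feature_mode)
  vals <- matrix$values
  tr_t <- intersect(train_samples, group_samples(matrix, "tumor"))
  tr_n <- intersect(train_samples, group_samples(matrix, "normal"))
  x <- base::matrix(NA_real_, ncol(vals), length(panel),
                    dimnames = list(colnames(vals), panel))
  probes <- stats::setNames(rep(NA_character_, length(panel)), panel)
  for (g in panel) {
    pr <- manifest$probe[manifest$gene == g]
    pr <- intersect(pr, rownames(vals))
    if (length(pr) == 0) stop("panel gene has no probes in matrix: ", g)
    if (feature_mode == "probe") {
      dbeta <- vapply(pr, function(p) {
        mean(vals[p, tr_t], na.rm = TRUE) - mean(vals[p, tr_n], na.rm = TRUE)
      }, 0)
      best <- pr[order(-abs(dbeta), pr)][1]
      probes[[g]] <- best
      x[, g] <- vals[best, ]
    } else {
      x[, g] <- colMeans(vals[pr, , drop = FALSE], na.rm = TRUE)
    }
  }
  # impute missing with training medians only (no leakage from test rows)
  for (g in panel) {
    miss <- is.na(x[, g])
    if (any(miss)) {
      med <- stats::median(x[train_samples, g], na.rm = TRUE)
      x[miss, g] <- med
    }
  }
  structure(list(x = x, y = unname(matrix$groups[rownames(x)]),
                 probes = probes, cancer = cancer),
            class = "feature_table")
}

#' Classification metrics from truth and prediction labels
#'
#' Tumor is the positive class. `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)`, `F = 2PR/(P+R)`. When the test set has no
#' normals (all positive), precision is 1 by construction if anything is
#' called positive, recall equals accuracy, and the report is flagged.
#'
#' @param truth,pred Character vectors of `"tumor"` / `"normal"` labels.
#' @return List: accuracy, recall, precision, f_score, tp/fp/tn/fn, flag.
#' @export
classification_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  tp <- sum(truth == "tumor" & pred == "tumor")
  fp <- sum(truth == "normal" & pred == "tumor")
  tn <- sum(truth == "normal" & pred == "normal")
  fn <- sum(truth == "tumor" & pred == "normal")
  accuracy <- (tp + tn) / length(truth)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f_score <- if (!is.na(recall) && !is.na(precision) &&
                 (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  flag <- if (tn + fp == 0) "no_negatives_in_test" else NA_character_
  list(accuracy = accuracy, recall = recall, precision = precision,
       f_score = f_score, tp = tp, fp = fp, tn = tn, fn = fn, flag = flag)
}

# stratified index split; deterministic given seed
stratified_split <- function(y, train_fraction, seed) {
  set.seed(seed)
  train <- unlist(lapply(unique(sort(y)), function(cl) {
    idx <- which(y == cl)
    n_tr <- max(1L, floor(length(idx) * train_fraction))
    sample(idx, n_tr)
  }), use.names = FALSE)
  sort(train)
}

#' Train and evaluate an SVM for one panel on one cancer
#'
#' Stratified train/test split (fraction and seed from the config),
#' representative-probe choice and feature standardization computed on the
#' training rows only, RBF SVM with balanced class weights, metrics on the
#' held-out rows with tumor as positive class.
#'
#' @param matrix A `BetaMatrix`.
#' @param manifest A `ProbeManifest`.
#' @param panel Character vector of panel genes.
#' @param config A [meth_config()].
#' @param cancer Cancer label for the report.
#' @return A list of class `"eval_report"`: panel, cancer, seed, metrics
#'   (accuracy, recall, precision, f_score), confusion counts, n_train,
#'   n_test, flag.
#' @export
train_eval <- function(matrix, manifest, panel, config = meth_config(),
                       cancer = NA_character_) {
  samples <- colnames(matrix$values)
  y_all <- unname(matrix$groups[samples])
  tr_idx <- stratified_split(y_all, config$train_fraction, config$seed)
  train_samples <- samples[tr_idx]
  test_samples <- setdiff(samples, train_samples)
  if (length(unique(y_all[tr_idx])) < 2) stop("single-class training set")
  ft <- extract_features(matrix, manifest, panel,
                         train_samples = train_samples,
                         feature_mode = config$feature_mode,
                         cancer = cancer)
  fit <- fit_panel_model(ft, train_samples, config)
  pred <- predict_panel_model(fit, ft, test_samples)
  met <- classification_metrics(unname(matrix$groups[test_samples]), pred)
  structure(c(list(panel = panel, cancer = cancer, seed = config$seed,
                   probes = ft$probes, n_train = length(train_samples),
                   n_test = length(test_samples)), met),
            class = "eval_report")
}

# standardize on training rows, fit SVM; returns model + scaling
fit_panel_model <- function(ft, train_samples, config) {
  xtr <- ft$x[train_samples, , drop = FALSE]
  ctr <- colMeans(xtr)
  sds <- apply(xtr, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  xs <- sweep(sweep(xtr, 2, ctr), 2, sds, "/")
  ytr <- ifelse(ft$y[match(train_samples, rownames(ft$x))] == "tumor", 1, -1)
  model <- svm_fit(xs, ytr, cost = config$svm_cost, gamma = config$svm_gamma)
  list(model = model, center = ctr, scale = sds)
}

predict_panel_model <- function(fit, ft, samples) {
  xte <- ft$x[samples, , drop = FALSE]
  xs <- sweep(sweep(xte, 2, fit$center), 2, fit$scale, "/")
  ifelse(predict(fit$model, xs) == 1, "tumor", "normal")
}

#' Evaluate every panel across cancers
#'
#' Runs [train_eval()] for each enumerated panel on each cancer and averages
#' the per-cancer test accuracies, the quantity [select_optimal()] ranks.
#'
#' @param matrices Named list of `BetaMatrix` objects (one per cancer).
#' @param manifests A single `ProbeManifest` or named list parallel to
#'   `matrices`.
#' @param groups A `"functional_groups"` object.
#' @param config A [meth_config()].
#' @return List of summaries: panel, mean_accuracy, per_cancer (list of
#'   `eval_report`s).
#' @export
evaluate_panels <- function(matrices, manifests, groups,
                            config = meth_config()) {
  panels <- enumerate_panels(groups)
  one_manifest <- inherits(manifests, "ProbeManifest")
  lapply(panels, function(panel) {
    reports <- lapply(names(matrices), function(cn) {
      mf <- if (one_manifest) manifests else manifests[[cn]]
      train_eval(matrices[[cn]], mf, panel, config, cancer = cn)
    })
    names(reports) <- names(matrices)
    list(panel = panel,
         mean_accuracy = mean(vapply(reports, `[[`, 0, "accuracy")),
         per_cancer = reports)
  })
}

#' Select the optimal panel from evaluation summaries
#'
#' Argmax of the cross-cancer average accuracy; ties prefer fewer genes,
#' then the lexicographically smallest panel.
#'
#' @param reports List as returned by [evaluate_panels()] (each element
#'   needs `panel` and `mean_accuracy`).
#' @return The winning summary (with `panel` and `mean_accuracy`).
#' @export
select_optimal <- function(reports) {
  stopifnot(length(reports) >= 1)
  acc <- vapply(reports, `[[`, 0, "mean_accuracy")
  sizes <- vapply(reports, function(r) length(r$panel), 0L)
  keys <- vapply(reports, function(r) {
    paste(sort(r$panel), collapse = "|")
  }, "")
  ord <- order(-acc, sizes, keys)
  reports[[ord[1]]]
}

#' Universal cross-cancer model
#'
#' Pools the training cancers' feature tables into one SVM (standardization
#' on the pooled pool) and evaluates it on each held-out cancer separately.
#' All tables must share the same panel columns.
#'
#' @param train_tables Named list of `feature_table`s (training cancers).
#' @param test_tables Named list of `feature_table`s (held-out cancers);
#'   empty tables are an error.
#' @param config A [meth_config()].
#' @return Named list of `eval_report`-like metric lists, one per test
#'   cancer.
#' @export
universal_model <- function(train_tables, test_tables,
                            config = meth_config()) {
  stopifnot(length(train_tables) >= 1, length(test_tables) >= 1)
  panel <- colnames(train_tables[[1]]$x)
  for (tb in c(train_tables, test_tables)) {
    if (!identical(colnames(tb$x), panel)) {
      stop("feature mismatch: all tables must share the same panel columns")
    }
    if (nrow(tb$x) == 0) stop("empty feature table")
  }
  xtr <- do.call(rbind, lapply(train_tables, `[[`, "x"))
  ytr <- unlist(lapply(train_tables, `[[`, "y"), use.names = FALSE)
  if (length(unique(ytr)) < 2) stop("single-class training set")
  ctr <- colMeans(xtr)
  sds <- apply(xtr, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  xs <- sweep(sweep(xtr, 2, ctr), 2, sds, "/")
  model <- svm_fit(xs, ifelse(ytr == "tumor", 1, -1),
                   cost = config$svm_cost, gamma = config$svm_gamma)
  out <- lapply(test_tables, function(tb) {
    xte <- sweep(sweep(tb$x, 2, ctr), 2, sds, "/")
    pred <- ifelse(predict(model, xte) == 1, "tumor", "normal")
    met <- classification_metrics(tb$y, pred)
    structure(c(list(panel = panel, cancer = tb$cancer,
                     seed = config$seed,
                     n_train = nrow(xtr), n_test = nrow(tb$x)), met),
              class = "eval_report")
  })
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("panel [%s] on %s: acc %.3f recall %.3f precision %.3f F %.3f\n",
              paste(x$panel, collapse = ", "), x$cancer, x$accuracy,
              x$recall, x$precision, x$f_score))
  invisible(x)
}
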