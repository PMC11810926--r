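#' Interquartile-range outlier filter (Tukey fences)
#'
#' Retains values v with `Q1 - k*IQR <= v <= Q3 + k*IQR`, quartiles by linear
#' interpolation (type-7). With fewer than 4 finite values the input is
#' returned unchanged and flagged (attribute `filtered = FALSE`). `k = Inf`
#' is the identity. The filter is idempotent only in the sense required here
#' (it is re-applied per probe once); note a second application can tighten
#' fences on the reduced sample, so idempotence is asserted on data whose
#' inliers are well separated from outliers.
#'
#' @param values Numeric vector of beta-values (non-finite entries retained).
#' @param k Fence multiplier, default 1.5.
#' @return Filtered vector, order preserved, with attribute `filtered`.
#' @export
iqr_filter <- function(values, k = 1.5) {
  stopifnot(k >= 0)
  fin <- is.finite(values)
  if (sum(fin) < 4) {
    out <- values
    attr(out, "filtered") <- FALSE
    return(out)
  }
  q <- stats::quantile(values[fin], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  half <- if (is.infinite(k)) Inf else if (iqr == 0) 0 else k * iqr
  keep <- !fin | (values >= q[1] - half & values <= q[2] + half)
  out <- values[keep]
  attr(out, "filtered") <- TRUE
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH q-values with monotonicity enforcement.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

# Welch two-sided t-test p-value; degenerate zero-variance inputs resolve to
# p = 1 (equal means) or p = 0 (different means) rather than NaN.
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  2 * stats::pt(-abs(tt), df)
}

#' Per-probe differential methylation statistics
#'
#' For every probe, outliers are removed within each group separately via
#' [iqr_filter()]; the probe is dropped (and listed in attribute `dropped`)
#' if either group keeps fewer than `min_group_size_after_outliers` samples.
#' Delta-beta is mean(tumor) - mean(normal) on the retained values, the
#' p-value a two-sided Welch t-test, and q-values are BH-adjusted across all
#' surviving probes. Volcano classes follow [classify_volcano()].
#'
#' @param matrix A `BetaMatrix`.
#' @param manifest A `ProbeManifest` (probes absent from it get `NA` gene and
#'   region `"other"`).
#' @param config A [meth_config()].
#' @return data.frame of class `"probe_records"` with columns probe, gene,
#'   region, delta_beta, p_value, q_value, n_tumor_used, n_normal_used,
#'   volcano_class.
#' @export
probe_stats <- function(matrix, manifest, config = meth_config()) {
  stopifnot(inherits(matrix, "BetaMatrix"))
  tum <- group_samples(matrix, "tumor")
  nor <- group_samples(matrix, "normal")
  if (length(tum) == 0 || length(nor) == 0) stop("empty group")
  probes <- rownames(matrix$values)
  n <- length(probes)
  delta <- p <- numeric(n)
  nt <- nn <- integer(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    xt <- matrix$values[i, tum]; xt <- xt[is.finite(xt)]
    xn <- matrix$values[i, nor]; xn <- xn[is.finite(xn)]
    xt <- iqr_filter(xt, config$iqr_k)
    xn <- iqr_filter(xn, config$iqr_k)
    nt[i] <- length(xt); nn[i] <- length(xn)
    if (nt[i] < config$min_group_size_after_outliers ||
        nn[i] < config$min_group_size_after_outliers) next
    delta[i] <- mean(xt) - mean(xn)
    p[i] <- welch_p(xt, xn)
    keep[i] <- TRUE
  }
  dropped <- probes[!keep]
  rec <- data.frame(
    probe = probes[keep],
    delta_beta = delta[keep],
    p_value = p[keep],
    q_value = bh_adjust(p[keep]),
    n_tumor_used = nt[keep],
    n_normal_used = nn[keep],
    stringsAsFactors = FALSE
  )
  idx <- match(rec$probe, manifest$probe)
  rec$gene <- manifest$gene[idx]
  rec$region <- ifelse(is.na(idx), "other", manifest$region[idx])
  rec$volcano_class <- classify_volcano(rec$delta_beta, rec$q_value,
                                        rec$region, config)
  rec <- rec[, c("probe", "gene", "region", "delta_beta", "p_value",
                 "q_value", "n_tumor_used", "n_normal_used",
                 "volcano_class")]
  attr(rec, "dropped") <- dropped
  class(rec) <- c("probe_records", "data.frame")
  rec
}

#' Volcano-plot class of probes
#'
#' A probe is a DMP when `|delta_beta| >= dmp_abs_dbeta_threshold` and
#' `q < dmp_q_threshold`. DMPs in promoter regions are classed `"promoter"`
#' (promoter overrides the hyper/hypo color); remaining DMPs are `"hyper"`
#' (positive delta-beta) or `"hypo"` (negative); everything else `"other"`.
#'
#' @param delta_beta,q_value,region Vectors of equal length.
#' @param config A [meth_config()].
#' @return Character vector in `{hyper, hypo, promoter, other}`.
#' @export
classify_volcano <- function(delta_beta, q_value, region,
                             config = meth_config()) {
  is_dmp <- abs(delta_beta) >= config$dmp_abs_dbeta_threshold &
    q_value < config$dmp_q_threshold
  out <- rep("other", length(delta_beta))
  out[is_dmp & delta_beta > 0] <- "hyper"
  out[is_dmp & delta_beta < 0] <- "hypo"
  out[is_dmp & region == "promoter"] <- "promoter"
  out
}

#' Call primary-biomarker genes from probe records
#'
#' A gene qualifies when it has at least one probe with
#' `|delta_beta| > dmp_abs_dbeta_threshold` (strict), `q < gene_q_threshold`,
#' and — when `promoter_only` — a promoter-region location. The gene's
#' reported delta-beta is the signed value of its max-|delta-beta|
#' qualifying probe; status is `hyper` iff that value is positive.
#'
#' @param records A `probe_records` data.frame.
#' @param config A [meth_config()].
#' @param cancer Cancer label attached to the result.
#' @return A `"marker_set"` data.frame (gene, delta_beta, status, probe) with
#'   attributes `cancer` and `provenance = "primary"`.
#' @export
call_primary_markers <- function(records, config = meth_config(),
                                 cancer = NA_character_) {
  ok <- !is.na(records$gene) &
    abs(records$delta_beta) > config$dmp_abs_dbeta_threshold &
    records$q_value < config$gene_q_threshold
  if (isTRUE(config$promoter_only)) ok <- ok & records$region == "promoter"
  qual <- records[ok, , drop = FALSE]
  if (nrow(qual) == 0) {
    return(marker_set(data.frame(gene = character(), delta_beta = numeric(),
                                 status = character(), probe = character(),
                                 stringsAsFactors = FALSE),
                      cancer = cancer, provenance = "primary"))
  }
  qual <- qual[order(qual$gene, -abs(qual$delta_beta), qual$probe), ]
  best <- qual[!duplicated(qual$gene), ]
  marker_set(data.frame(
    gene = best$gene,
    delta_beta = best$delta_beta,
    status = ifelse(best$delta_beta > 0, "hyper", "hypo"),
    probe = best$probe,
    stringsAsFactors = FALSE
  ), cancer = cancer, provenance = "primary")
}

#' Volcano plot of probe records
#'
#' Delta-beta against -log10(p), colored by volcano class: hypermethylated
#' DMPs light green, hypomethylated red, promoter-region DMPs black,
#' remaining probes grey.
#'
#' @param records A `probe_records` data.frame.
#' @param ... Passed to [graphics::plot()].
#' @return The records, invisibly.
#' @export
plot_volcano <- function(records, ...) {
  cols <- c(hyper = "lightgreen", hypo = "red", promoter = "black",
            other = "grey70")
  logp <- -log10(pmax(records$p_value, .Machine$double.xmin))
  graphics::plot(records$delta_beta, logp,
                 col = cols[records$volcano_class], pch = 16,
                 xlab = expression(Delta * beta),
                 ylab = expression(-log[10](p)), ...)
  invisible(records)
}
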