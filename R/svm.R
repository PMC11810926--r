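#' Soft-margin RBF support vector machine (SMO solver)
#'
#' Compact, dependency-free sequential minimal optimization for the binary
#' soft-margin SVM dual, sufficient for the panel sizes this package
#' evaluates (hundreds of subjects, a handful of features). Deterministic:
#' the second working-set index is chosen by maximum |E_i - E_j| with
#' first-index tie-break, so repeated fits on identical data are
#' bit-identical.
#'
#' @param x Numeric feature matrix (subjects x features), already
#'   standardized by the caller.
#' @param y Labels: +1 / -1 numeric vector (tumor = +1).
#' @param cost Soft-margin cost C.
#' @param gamma RBF width; `NULL` gives 1 / (ncol(x) * var(x)) (overall
#'   feature variance), the common "scale" heuristic.
#' @param class_weights `"balanced"` rescales C per class by n / (2 * n_k),
#'   or a named numeric vector `c("1" = ..., "-1" = ...)`, or `NULL`.
#' @param tol KKT violation tolerance.
#' @param max_sweeps Hard cap on full passes over the data.
#' @return An object of class `"methmark_svm"`.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL,
                    class_weights = "balanced", tol = 1e-3,
                    max_sweeps = 200L) {
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("single-class training set")
  n <- nrow(x)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v == 0) v <- 1
    gamma <- 1 / (ncol(x) * v)
  }
  C <- rep(cost, n)
  if (identical(class_weights, "balanced")) {
    tab <- table(factor(y, levels = c(-1, 1)))
    w <- n / (2 * as.numeric(tab))
    names(w) <- c("-1", "1")
    C <- cost * w[as.character(y)]
  } else if (is.numeric(class_weights)) {
    C <- cost * class_weights[as.character(y)]
  }
  C <- unname(C)
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n)
  b <- 0
  E <- -y   # f(x) = 0 initially
  sweeps <- 0L
  repeat {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- E[i]
      if (!((y[i] * Ei < -tol && alpha[i] < C[i]) ||
            (y[i] * Ei > tol && alpha[i] > 0))) next
      j <- which.max(abs(E - Ei))
      if (j == i) next
      Ej <- E[j]
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (y[i] != y[j]) {
        L <- max(0, aj_old - ai_old)
        H <- min(C[j], C[i] + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C[i])
        H <- min(C[j], ai_old + aj_old)
      }
      if (L >= H) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- aj_old - y[j] * (Ei - Ej) / eta
      aj <- min(max(aj, L), H)
      if (abs(aj - aj_old) < 1e-8) next
      ai <- ai_old + y[i] * y[j] * (aj_old - aj)
      b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
        y[j] * (aj - aj_old) * K[i, j]
      b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
        y[j] * (aj - aj_old) * K[j, j]
      b_new <- if (ai > 0 && ai < C[i]) b1
               else if (aj > 0 && aj < C[j]) b2
               else (b1 + b2) / 2
      E <- E + y[i] * (ai - ai_old) * K[, i] +
        y[j] * (aj - aj_old) * K[, j] + (b_new - b)
      alpha[i] <- ai; alpha[j] <- aj; b <- b_new
      changed <- changed + 1L
    }
    sweeps <- sweeps + 1L
    if (changed == 0L || sweeps >= max_sweeps) break
  }
  sv <- alpha > 1e-8
  structure(list(sv_x = x[sv, , drop = FALSE], sv_ay = (alpha * y)[sv],
                 b = b, gamma = gamma, sweeps = sweeps),
            class = "methmark_svm")
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Predict with a fitted SVM
#' @param object A `"methmark_svm"`.
#' @param newdata Feature matrix on the training scale.
#' @param ... Unused.
#' @return Numeric vector of +1 / -1 predictions.
#' @export
predict.methmark_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(object$sv_x) == 0) return(rep(sign(object$b + 0.5), nrow(newdata)))
  f <- rbf_kernel(newdata, object$sv_x, object$gamma) %*% object$sv_ay +
    object$b
  ifelse(as.vector(f) >= 0, 1, -1)
}
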