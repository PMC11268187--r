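#' Fit a linear support vector machine in the dual
#'
#' Soft-margin linear SVM: minimize `0.5 ||beta||^2 + C sum(zeta_j)` subject
#' to `y_j (x_j' beta + b) >= 1 - zeta_j`, solved in the Lagrangian dual by
#' sequential minimal optimization over maximal-violating pairs with a
#' linear kernel. At the solution the dual coefficients satisfy the box
#' constraints `0 <= alpha_j <= C` and the equality `sum(alpha_j y_j) = 0`;
#' the hyperplane normal is recovered as `beta = sum(alpha_j y_j x_j)` and
#' the bias from the free support vectors.
#'
#' @param x Numeric matrix, trials x features (or a `feature_matrix`).
#' @param y Two-class labels; the lower sorted class maps to -1 and the
#'   higher to +1. Ignored when `x` is a `feature_matrix`.
#' @param C Box constraint (> 0), default 1.
#' @param tol Stopping tolerance on the maximal KKT violation, default
#'   1e-5.
#' @param max_iter Iteration cap; exceeding it raises a labeled error
#'   reporting the residual violation.
#' @return An `svm_model` with `beta`, `bias`, `alpha`, `support_indices`,
#'   `slack`, the label mapping and convergence diagnostics.
#' @export
fit_linear_svm <- function(x, y = NULL, C = 1, tol = 1e-5,
                           max_iter = 100000L) {
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    pt_stop("pt_input_error", "linear SVM requires exactly two classes")
  }
  if (C <= 0) pt_stop("pt_input_error", "box constraint C must be positive")
  yy <- ifelse(y == classes[2], 1, -1)
  n <- nrow(x)
  Kmat <- tcrossprod(x)
  alpha <- numeric(n)
  grad <- rep(-1, n)          # gradient of the dual objective at alpha = 0
  eps <- 1e-12
  it <- 0L
  repeat {
    up <- (yy > 0 & alpha < C - eps) | (yy < 0 & alpha > eps)
    low <- (yy > 0 & alpha > eps) | (yy < 0 & alpha < C - eps)
    gy <- -yy * grad
    m_up <- max(gy[up]); i <- which(up)[which.max(gy[up])]
    m_low <- min(gy[low])
    if (m_up - m_low < tol) break
    # second-order working-set selection: pair i with the j giving the
    # largest decrease of the dual objective
    cand <- which(low & gy < m_up)
    bvec <- m_up - gy[cand]
    qvec <- pmax(Kmat[i, i] + diag(Kmat)[cand] - 2 * Kmat[i, cand], 1e-12)
    j <- cand[which.max(bvec^2 / qvec)]
    it <- it + 1L
    if (it > max_iter) {
      pt_stop("pt_convergence_error",
              "SVM dual did not converge in %d iterations (violation %.3g)",
              max_iter, m_up - m_low)
    }
    quad <- Kmat[i, i] + Kmat[j, j] - 2 * Kmat[i, j]
    delta <- (m_up - gy[j]) / max(quad, 1e-12)
    # step along the equality constraint: alpha_i y_i increases, alpha_j
    # y_j decreases by the same amount, clipped to the box
    step <- delta
    step <- min(step,
                if (yy[i] > 0) C - alpha[i] else alpha[i],
                if (yy[j] > 0) alpha[j] else C - alpha[j])
    # v = alpha * y moves by +step at i and -step at j, preserving sum(v)
    alpha[i] <- alpha[i] + yy[i] * step
    alpha[j] <- alpha[j] - yy[j] * step
    grad <- grad + yy * (Kmat[, i] - Kmat[, j]) * step
  }
  v <- alpha * yy
  f0 <- as.numeric(Kmat %*% v)
  free <- alpha > eps & alpha < C - eps
  bias <- if (any(free)) {
    mean(yy[free] - f0[free])
  } else {
    (m_up + m_low) / 2
  }
  beta <- as.numeric(crossprod(x, v))
  slack <- pmax(0, 1 - yy * (f0 + bias))
  structure(list(
    beta = beta, bias = bias, alpha = alpha, C = C,
    support_indices = which(alpha > eps), slack = slack,
    classes = classes, y_signed = yy, iterations = it,
    kkt_violation = m_up - m_low
  ), class = "svm_model")
}

#' Decision values and class predictions from a linear SVM
#'
#' @param model An `svm_model`.
#' @param newx Observations (matrix rows or single vector, or a
#'   `feature_matrix`).
#' @return List with `class` (labels on the original scale) and `decision`
#'   (signed distance-scaled values `x' beta + b`).
#' @export
predict_svm <- function(model, newx) {
  if (inherits(newx, "feature_matrix")) newx <- newx$x
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != length(model$beta)) {
    pt_stop("pt_input_error", "feature dimension mismatch")
  }
  f <- as.numeric(newx %*% model$beta + model$bias)
  cls <- ifelse(f >= 0, model$classes[2], model$classes[1])
  list(class = cls, decision = f)
}

#' Geometric margin width of a fitted linear SVM
#'
#' The width of the band separating the two margins, `2 / ||beta||`.
#'
#' @param model An `svm_model` with a nonzero normal vector.
#' @return Positive scalar.
#' @export
svm_margin_width <- function(model) {
  stopifnot(inherits(model, "svm_model"))
  nb <- sqrt(sum(model$beta^2))
  if (nb == 0) {
    pt_stop("pt_input_error",
            "margin width undefined: the hyperplane normal is zero")
  }
  2 / nb
}
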