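#' Fit a Gaussian linear discriminant model
#'
#' Both classes are modeled as Gaussians sharing one covariance matrix:
#' class means are the sample means and the pooled within-class covariance
#' S is shrunk toward its diagonal, `(1 - lambda) S + lambda diag(S)`, to
#' stay positive definite when the feature dimension (up to 9000 here)
#' exceeds the sample count. Priors are the empirical class frequencies by
#' default. The shrunk covariance is never formed explicitly: Mahalanobis
#' solves go through the Woodbury identity on the n-dimensional factor, so
#' fitting stays O(n^2 p). With `lambda = 0` and p > n a pseudo-inverse
#' (SVD) fallback is used. Features with zero pooled variance are dropped
#' from the discriminant (recorded in the model).
#'
#' @param x Numeric matrix, trials x features (or a `feature_matrix`).
#' @param y Class labels (two or more classes; each with >= 2 samples).
#'   Ignored when `x` is a `feature_matrix`.
#' @param lambda Diagonal shrinkage intensity in `[0, 1]`, default 0.5.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return An `lda_model` with `means`, `priors`, `lambda`, the diagonal of
#'   the pooled covariance, and the factored solver state.
#' @export
fit_lda <- function(x, y = NULL, lambda = 0.5,
                    priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  if (lambda < 0 || lambda > 1) {
    pt_stop("pt_input_error", "lambda must lie in [0, 1]")
  }
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) pt_stop("pt_input_error", "need at least two classes")
  nk <- vapply(classes, function(k) sum(y == k), 0L)
  if (any(nk < 2)) {
    pt_stop("pt_input_error", "every class needs at least 2 samples")
  }
  n <- nrow(x); p <- ncol(x); df <- n - K
  means <- t(vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
                    numeric(p)))
  xc <- x - means[match(y, classes), , drop = FALSE]
  d_full <- colSums(xc^2) / df
  keep <- d_full > max(d_full, .Machine$double.eps) * 1e-12
  pr <- if (priors == "empirical") nk / n else rep(1 / K, K)

  model <- structure(list(
    classes = classes, means = means, priors = pr, lambda = lambda,
    n = n, df = df, keep = keep, pooled_diag = d_full,
    xc = xc[, keep, drop = FALSE]
  ), class = "lda_model")

  dk <- d_full[keep]
  if (any(keep)) {
    if (lambda == 1) {
      model$solver <- "diag"
    } else if (lambda > 0) {
      # Sigma = lambda*D + c * Xc' Xc with c = (1-lambda)/df; Woodbury on
      # the n x n inner matrix M = I/c + Xc D^{-1} Xc' (D = lambda * diag)
      A <- lambda * dk
      W <- sweep(model$xc, 2, A, "/")            # n x p : Xc A^{-1}
      cconst <- (1 - lambda) / df
      M <- tcrossprod(W, model$xc) + diag(n) / cconst
      model$solver <- "woodbury"
      model$A <- A
      model$W <- W
      model$M_chol <- chol((M + t(M)) / 2)
    } else {
      sv <- svd(model$xc, nu = 0)
      pos <- sv$d > max(sv$d) * 1e-10
      model$solver <- "pinv"
      model$V <- sv$v[, pos, drop = FALSE]
      model$inv_eig <- df / sv$d[pos]^2          # eigenvalues of Sigma^+
    }
  } else {
    model$solver <- "none"   # all features degenerate: priors-only model
  }
  model
}

# Solve Sigma^{-1} B for a p_keep x m matrix B (kept features only).
lda_solve <- function(model, B) {
  switch(model$solver,
    diag = B / model$pooled_diag[model$keep],
    woodbury = {
      B_over_A <- B / model$A
      rhs <- model$xc %*% B_over_A                     # n x m
      z <- backsolve(model$M_chol,
                     forwardsolve(t(model$M_chol), rhs))
      B_over_A - t(model$W) %*% z
    },
    pinv = model$V %*% (model$inv_eig * crossprod(model$V, B)),
    none = B * 0
  )
}

#' Classify observations with a fitted LDA model
#'
#' The class-conditional density `P(x | k)` is the shared-covariance
#' Gaussian, entirely determined by the Mahalanobis distance of `x` from
#' the class mean; posteriors follow from Bayes' theorem with the pooled
#' normalizer, and the predicted class minimizes the expected 0-1
#' misclassification cost (i.e. the maximum-posterior class). Exact
#' posterior ties resolve to the lower class index.
#'
#' @param model An `lda_model` from [fit_lda()].
#' @param newx Matrix of observations (rows) or a single vector; the
#'   feature dimension must match the training data.
#' @return List with `class` (predicted labels) and `posterior`
#'   (rows x classes matrix).
#' @export
predict_lda <- function(model, newx) {
  if (inherits(newx, "feature_matrix")) newx <- newx$x
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != ncol(model$means)) {
    pt_stop("pt_input_error",
            "feature dimension %d does not match the model (%d)",
            ncol(newx), ncol(model$means))
  }
  K <- length(model$classes)
  n <- nrow(newx)
  log_lik <- matrix(0, n, K)
  for (k in seq_len(K)) {
    D <- sweep(newx[, model$keep, drop = FALSE], 2,
               model$means[k, model$keep], "-")
    Q <- lda_solve(model, t(D))
    log_lik[, k] <- -0.5 * colSums(t(D) * Q)
  }
  # log of P(x|k) P(k), with the Gaussian constant shared across classes
  sc <- sweep(log_lik, 2, log(model$priors), "+")
  # pooled normalizer: P(x) = sum_k P(x|k)
  mx <- apply(log_lik, 1, max)
  log_px <- mx + log(rowSums(exp(log_lik - mx)))
  posterior <- exp(sc - log_px)
  colnames(posterior) <- as.character(model$classes)
  idx <- apply(sc, 1, which.max)   # first max = lower class index on ties
  list(class = model$classes[idx], posterior = posterior)
}

#' Euclidean distance between the two class means of an LDA model
#'
#' A separability index in Z-scored feature space that, unlike accuracy,
#' does not saturate once the classes are fully separated.
#'
#' @param model A two-class `lda_model`.
#' @return Nonnegative scalar.
#' @export
lda_distance <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  if (length(model$classes) != 2) {
    pt_stop("pt_input_error",
            "LDA distance is defined for two-class models only")
  }
  sqrt(sum((model$means[1, ] - model$means[2, ])^2))
}
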