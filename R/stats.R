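new_test_result <- function(method, statistic, p_value, effect_size,
                            n_per_group, mode, note = NULL) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, effect_size = effect_size,
                 n_per_group = n_per_group, mode = mode, note = note),
            class = "emg_test_result")
}

#' @export
print.emg_test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g, %s = %.3f (n = %s, %s)\n",
              x$method, names(x$statistic)[1], x$statistic[1], x$p_value,
              names(x$effect_size)[1], x$effect_size[1],
              paste(x$n_per_group, collapse = "/"), x$mode))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Mann-Whitney U of the first sample from midranks: number of (a, b) pairs
# with a > b, ties counting one half.
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Wilcoxon rank sum test with exact small-sample p-values
#'
#' Two-sided rank sum test comparing two independent samples. The reported
#' statistic W is the Mann-Whitney U of the first sample (its minimum, 0,
#' occurs when every value of `a` lies below every value of `b`). In exact
#' mode -- the default whenever `length(a) + length(b) <= 12` -- the null
#' distribution is built by full enumeration of all `choose(na+nb, na)`
#' group assignments of the pooled midranks, so e.g. two fully separated
#' groups of five give p = 2/252. Beyond that, a normal approximation with
#' tie correction and continuity correction is used. The rank-biserial
#' correlation is attached as the effect size.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param mode `"auto"` (exact when na + nb <= 12), `"exact"` or
#'   `"normal"`.
#' @return An `emg_test_result` with statistic `W`, two-sided `p_value`,
#'   effect size `r_rb` and the group sizes.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) {
    pt_stop("pt_input_error", "both samples must be non-empty")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  if (mode == "auto") mode <- if (n <= 12) "exact" else "normal"
  r <- rank(c(a, b))
  ties <- anyDuplicated(c(a, b)) > 0
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  note <- NULL
  if (mode == "exact") {
    if (ties) note <- "ties present: exact enumeration uses midranks"
    combs <- utils::combn(n, na)
    rs <- colSums(matrix(r[combs], nrow = na))
    u_all <- rs - na * (na + 1) / 2
    tol <- 1e-8
    p <- 2 * min(mean(u_all <= u_obs + tol), mean(u_all >= u_obs - tol))
    p <- min(p, 1)
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 *
      (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(max(sigma2, 1e-300))
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  new_test_result("Wilcoxon rank sum", c(W = u_obs), p,
                  c(r_rb = rank_biserial(a, b)), c(na, nb), mode, note)
}

#' Rank-biserial correlation
#'
#' Effect size for the rank sum test: the difference between the proportion
#' of (a, b) pairs with `b > a` and with `a > b`; ties contribute zero.
#' Equals +1 when every `b` exceeds every `a` and -1 in the reverse case.
#'
#' @param a,b Numeric samples.
#' @return Scalar in `[-1, 1]`.
#' @export
rank_biserial <- function(a, b) {
  if (!length(a) || !length(b)) {
    pt_stop("pt_input_error", "both samples must be non-empty")
  }
  ua <- u_statistic(a, b)          # pairs with a > b (+ half the ties)
  ub <- length(a) * length(b) - ua # pairs with b > a (+ half the ties)
  (ub - ua) / (length(a) * length(b))
}

#' Friedman rank test across repeated conditions
#'
#' Ranks conditions within each block (midranks on ties) and tests whether
#' the condition rank sums differ, with the tie-corrected chi-squared
#' statistic on `k - 1` degrees of freedom. When every block ranks the
#' conditions identically (no ties) the statistic reaches its maximum
#' `n (k - 1)`.
#'
#' @param blocks Numeric matrix, blocks (rows) x conditions (columns);
#'   at least 2 of each.
#' @return An `emg_test_result` with statistic `chisq`, `p_value`, effect
#'   size `W_K` (Kendall's W) and `c(n_blocks, k_conditions)`.
#' @export
friedman_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks); k <- ncol(blocks)
  if (n < 2 || k < 2) {
    pt_stop("pt_input_error", "need at least 2 blocks and 2 conditions")
  }
  r <- t(apply(blocks, 1, rank))
  tie_term <- sum(apply(blocks, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })) / (k - 1)
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tie_term
  if (den <= 0) {
    pt_warn("pt_degenerate_input",
            "all blocks fully tied: Friedman statistic set to 0")
    stat <- 0
  } else {
    stat <- num / den
  }
  p <- if (stat == 0) 1 else stats::pchisq(stat, df = k - 1,
                                           lower.tail = FALSE)
  w <- min(stat / (n * (k - 1)), 1)
  new_test_result("Friedman", c(chisq = stat), p, c(W_K = w),
                  c(n_blocks = n, k_conditions = k), mode = "chisq")
}

#' Kendall's coefficient of concordance
#'
#' Agreement of the block-wise rankings, computed from the (tie-corrected)
#' Friedman statistic as `W_K = chisq / (n (k - 1))`: 1 at perfect
#' concordance, 0 when condition columns are identical.
#'
#' @param blocks Numeric matrix, blocks x conditions.
#' @return Scalar in `[0, 1]`.
#' @export
kendalls_w <- function(blocks) {
  suppressWarnings(friedman_test(blocks))$effect_size[["W_K"]]
}

#' Ordinary least-squares slope of accuracy against angular distance
#'
#' Fits `y = intercept + slope * x` and reports the slope, intercept and
#' R-squared (defined as 0 when `y` is constant).
#'
#' @param x Angular distances in degrees (at least two distinct values).
#' @param y Accuracies (or any response).
#' @return A `slope_fit` list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_slope <- function(x, y) {
  if (length(unique(x)) < 2) {
    pt_stop("pt_input_error", "x must contain at least two distinct values")
  }
  stopifnot(length(x) == length(y))
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else 0,
                 n = length(x)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope %.4f (intercept %.3f, R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
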