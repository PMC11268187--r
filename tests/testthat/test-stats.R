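test_that("complete separation of two groups of five gives the printed exact result", {
  res <- wilcoxon_rank_sum(1:5, 6:10)
  expect_equal(unname(res$statistic), 0)           # U at its minimum
  expect_equal(res$p_value, 2 / 252)
  expect_equal(round(res$p_value, 3), 0.008)
  expect_equal(unname(res$effect_size), 1)
  expect_identical(res$mode, "exact")
})

test_that("identical samples give p = 1 and zero effect size", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_equal(unname(res$effect_size), 0)
})

test_that("exact p-values agree with enumeration for all small splits", {
  for (na in 2:6) {
    for (nb in 2:6) {
      vals <- phasictune:::with_seed(na * 10 + nb,
                                     stats::rnorm(na + nb))
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      got <- wilcoxon_rank_sum(a, b, mode = "exact")
      # independent oracle: base R's exact two-sided rank sum test
      ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(unname(got$statistic), unname(ref$statistic))
    }
  }
})

test_that("ranks drive the test: monotone transforms leave exact p unchanged", {
  a <- c(0.1, 0.5, 0.8, 1.2); b <- c(0.3, 0.9, 1.5, 2.2)
  p1 <- wilcoxon_rank_sum(a, b)$p_value
  p2 <- wilcoxon_rank_sum(exp(a), exp(b))$p_value
  expect_equal(p1, p2)
})

test_that("the normal approximation is sane at larger n", {
  phasictune:::with_seed(3, {
    a <- stats::rnorm(30); b <- stats::rnorm(30) + 1.2
    got <- wilcoxon_rank_sum(a, b)
    expect_identical(got$mode, "normal")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  })
})

test_that("rank-biserial correlation counts directional pairs", {
  expect_equal(rank_biserial(1:5, 6:10), 1)
  expect_equal(rank_biserial(6:10, 1:5), -1)
  expect_equal(rank_biserial(c(1, 2), c(1, 2)), 0)
  # brute-force pair counting on random data
  phasictune:::with_seed(11, {
    for (i in 1:5) {
      a <- sample(1:8, 5, replace = TRUE)
      b <- sample(1:8, 6, replace = TRUE)
      pairs <- outer(a, b, function(u, v) sign(v - u))
      expect_equal(rank_biserial(a, b), sum(pairs) / (5 * 6))
      expect_lte(abs(rank_biserial(a, b)), 1)
      expect_equal(rank_biserial(b, a), -rank_biserial(a, b))
    }
  })
})

test_that("Friedman reaches n(k-1) at perfect concordance and 0 on identical columns", {
  blocks <- matrix(rep(c(10, 20, 30), 7), 7, 3, byrow = TRUE) +
    phasictune:::with_seed(1, matrix(stats::runif(21, 0, 1), 7, 3))
  # construct strictly increasing rows so the ranking is identical
  blocks <- t(apply(blocks, 1, sort))
  res <- friedman_test(blocks)
  expect_equal(unname(res$statistic), 7 * 2)
  expect_equal(unname(res$effect_size), 1)
  same <- matrix(rep(stats::rnorm(5), 3), 5, 3)
  expect_warning(res0 <- friedman_test(same), class = "pt_degenerate_input")
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p_value, 1)
  expect_equal(suppressWarnings(kendalls_w(same)), 0)
})

test_that("Friedman matches base R on random tables, with and without ties", {
  for (seed in 1:6) {
    tab <- phasictune:::with_seed(seed, {
      m <- matrix(stats::rnorm(15), 5, 3)
      if (seed %% 2 == 0) m[1, ] <- c(1, 1, 2)  # introduce ties
      m
    })
    got <- friedman_test(tab)
    ref <- stats::friedman.test(tab)
    expect_equal(unname(got$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman is invariant to monotone within-block transforms", {
  tab <- phasictune:::with_seed(21, matrix(stats::rnorm(20), 5, 4))
  s1 <- friedman_test(tab)$statistic
  s2 <- friedman_test(exp(tab))$statistic
  expect_equal(s1, s2)
})

test_that("Kendall's W stays in [0, 1] on random tables", {
  for (seed in 1:10) {
    tab <- phasictune:::with_seed(100 + seed, matrix(stats::rnorm(12), 4, 3))
    w <- kendalls_w(tab)
    expect_gte(w, 0)
    expect_lte(w, 1)
  }
})

test_that("slope fits recover exact lines and match the closed form", {
  f <- fit_slope(c(15, 30, 45, 60), 0.3 * c(15, 30, 45, 60))
  expect_equal(f$slope, 0.3)
  expect_equal(f$r_squared, 1)
  fc <- fit_slope(c(15, 30, 45, 60), rep(0.7, 4))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
  phasictune:::with_seed(6, {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    f2 <- fit_slope(x, y)
    expect_equal(f2$slope, stats::cov(x, y) / stats::var(x))
    expect_equal(f2$r_squared, stats::cor(x, y)^2)
  })
  expect_error(fit_slope(rep(1, 5), 1:5), class = "pt_input_error")
})

test_that("empty samples and tiny tables raise labeled errors", {
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3),
               class = "pt_input_error")
  expect_error(rank_biserial(1:3, numeric(0)), class = "pt_input_error")
  expect_error(friedman_test(matrix(1, 1, 3)), class = "pt_input_error")
})
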