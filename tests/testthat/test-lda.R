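test_that("class means are the sample means; shrinkage endpoints behave", {
  x <- rbind(matrix(rep(c(1, 2), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(5, 7), 3), 3, 2, byrow = TRUE))
  y <- rep(0:1, each = 3)
  m <- fit_lda(x, y, lambda = 0.5)
  expect_equal(unname(m$means[1, ]), c(1, 2))
  expect_equal(unname(m$means[2, ]), c(5, 7))
  # lambda = 1: solver reduces to the diagonal of the pooled covariance
  d <- make_gaussian_task(n_per_class = 15, p = 3, seed = 2)
  m1 <- fit_lda(d$x, d$y, lambda = 1)
  expect_identical(m1$solver, "diag")
  xc <- d$x - m1$means[match(d$y, m1$classes), ]
  expect_equal(m1$pooled_diag, colSums(xc^2) / (nrow(d$x) - 2))
})

test_that("predictions follow the Gaussian-posterior rule computed by brute force", {
  for (seed in 1:5) {
    d <- make_gaussian_task(n_per_class = 25, p = 3, shift = 0.7,
                            seed = seed)
    lambda <- c(0, 0.3, 1)[seed %% 3 + 1]
    m <- fit_lda(d$x, d$y, lambda = lambda)
    xa <- phasictune:::with_seed(100 + seed,
                                 matrix(stats::rnorm(60), 20, 3))
    got <- predict_lda(m, xa)
    # independent direct evaluation: explicit pooled covariance, explicit
    # shrinkage, explicit Mahalanobis discriminant
    n0 <- sum(d$y == 0); n1 <- sum(d$y == 1)
    mu0 <- colMeans(d$x[d$y == 0, ]); mu1 <- colMeans(d$x[d$y == 1, ])
    xc <- rbind(sweep(d$x[d$y == 0, ], 2, mu0),
                sweep(d$x[d$y == 1, ], 2, mu1))
    S <- crossprod(xc) / (n0 + n1 - 2)
    Sh <- (1 - lambda) * S + lambda * diag(diag(S))
    Si <- solve(Sh)
    score <- function(z, mu, prior) {
      -0.5 * drop(t(z - mu) %*% Si %*% (z - mu)) + log(prior)
    }
    expected <- apply(xa, 1, function(z) {
      as.integer(score(z, mu1, n1 / (n0 + n1)) >
                   score(z, mu0, n0 / (n0 + n1)))
    })
    expect_equal(unname(got$class), expected)
  }
})

test_that("with n >> p and no shrinkage, predictions match MASS::lda", {
  skip_if_not_installed("MASS")
  for (seed in 1:10) {
    d <- make_gaussian_task(n_per_class = 30, p = 4, shift = 0.8,
                            seed = seed)
    m <- fit_lda(d$x, d$y, lambda = 0)
    ref <- MASS::lda(d$x, grouping = d$y)
    xa <- phasictune:::with_seed(200 + seed,
                                 matrix(stats::rnorm(25 * 4), 25, 4))
    expect_equal(unname(predict_lda(m, xa)$class),
                 as.integer(as.character(predict(ref, xa)$class)))
  }
})

test_that("equidistant points with equal priors break ties to the lower class", {
  x <- rbind(matrix(rep(c(-1, 0), 5), 5, 2, byrow = TRUE) +
               phasictune:::with_seed(1, matrix(stats::rnorm(10, 0, 0.1),
                                                5, 2)),
             matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE) +
               phasictune:::with_seed(2, matrix(stats::rnorm(10, 0, 0.1),
                                                5, 2)))
  y <- rep(c(3, 7), each = 5)  # arbitrary class labels
  m <- fit_lda(x, y, lambda = 1)
  # force exact symmetry: equal means mirrored around zero, so the origin
  # is equidistant
  m$means <- rbind(c(-1, 0), c(1, 0))
  m$priors <- c(0.5, 0.5)
  pr <- predict_lda(m, c(0, 0))
  expect_equal(pr$class, 3)
  # a point at a class mean goes to that class
  expect_equal(predict_lda(m, c(-1, 0))$class, 3)
  expect_equal(predict_lda(m, c(1, 0.01))$class, 7)
})

test_that("the p >> n shrunk solver agrees with the explicit dense inverse", {
  phasictune:::with_seed(31, {
    n <- 24; p <- 120
    x <- matrix(stats::rnorm(n * p), n, p)
    y <- rep(0:1, each = n / 2)
    x[y == 1, 1:10] <- x[y == 1, 1:10] + 1
    m <- fit_lda(x, y, lambda = 0.5)
    xa <- matrix(stats::rnorm(8 * p), 8, p)
    got <- predict_lda(m, xa)
    # dense reference (feasible at p = 120)
    mu <- m$means
    xc <- x - mu[match(y, m$classes), ]
    S <- crossprod(xc) / (n - 2)
    Sh <- 0.5 * S + 0.5 * diag(diag(S))
    Si <- solve(Sh)
    sc <- sapply(1:2, function(k) {
      D <- sweep(xa, 2, mu[k, ])
      -0.5 * rowSums((D %*% Si) * D) + log(m$priors[k])
    })
    expect_equal(unname(got$class), unname(m$classes[max.col(sc)]))
    # posterior ratios agree too
    post_ref <- exp(sc[, 2] - sc[, 1])
    post_got <- got$posterior[, 2] / got$posterior[, 1]
    expect_equal(unname(post_got), unname(post_ref), tolerance = 1e-6)
  })
})

test_that("LDA distance is the Euclidean distance between class means", {
  x <- rbind(matrix(0, 3, 2), matrix(rep(c(3, 4), 3), 3, 2, byrow = TRUE))
  y <- rep(0:1, each = 3)
  m <- fit_lda(x, y, lambda = 1)
  expect_equal(lda_distance(m), 5)
  # identical means
  m0 <- fit_lda(rbind(x[1:3, ], x[1:3, ]) +
                  phasictune:::with_seed(5, matrix(stats::rnorm(12, 0, 1e-8),
                                                   6, 2)),
                y, lambda = 1)
  expect_lt(lda_distance(m0), 1e-6)
  # translation invariance
  d <- make_gaussian_task(seed = 8)
  m1 <- fit_lda(d$x, d$y, lambda = 0.5)
  m2 <- fit_lda(d$x + 100, d$y, lambda = 0.5)
  expect_equal(lda_distance(m1), lda_distance(m2), tolerance = 1e-9)
})

test_that("degenerate inputs raise labeled errors", {
  d <- make_gaussian_task()
  expect_error(fit_lda(d$x, rep(0, nrow(d$x))), class = "pt_input_error")
  expect_error(fit_lda(d$x[c(1, 21:40), ], c(0, rep(1, 20))),
               class = "pt_input_error")
  expect_error(fit_lda(d$x, d$y, lambda = 2), class = "pt_input_error")
  m <- fit_lda(d$x, d$y)
  expect_error(predict_lda(m, numeric(3)), class = "pt_input_error")
  y3 <- c(rep(0, 13), rep(1, 13), rep(2, 14))
  m3 <- fit_lda(d$x, y3)
  expect_error(lda_distance(m3), class = "pt_input_error")
})

test_that("with equal priors and isotropic covariance LDA is nearest-class-mean", {
  phasictune:::with_seed(77, {
    mu <- rbind(c(0, 0, 0), c(2, 1, -1))
    x <- rbind(matrix(stats::rnorm(60), 20, 3) + rep(mu[1, ], each = 20),
               matrix(stats::rnorm(60), 20, 3) + rep(mu[2, ], each = 20))
    y <- rep(0:1, each = 20)
    m <- fit_lda(x, y, lambda = 0)
    # make the fitted covariance exactly isotropic and the priors equal
    m$priors <- c(0.5, 0.5)
    m$solver <- "diag"
    m$pooled_diag <- rep(1, 3)
    m$lambda <- 1
    xa <- matrix(stats::rnorm(90), 30, 3)
    got <- predict_lda(m, xa)$class
    d0 <- rowSums(sweep(xa, 2, m$means[1, ])^2)
    d1 <- rowSums(sweep(xa, 2, m$means[2, ])^2)
    expect_equal(unname(got), as.integer(d1 < d0))
  })
})
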