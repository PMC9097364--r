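test_that("pca_correlation matches the SVD oracle and projects fossils", {
  set.seed(11)
  X <- matrix(rnorm(300), 50, 6)
  res <- pca_correlation(X)
  expect_equal(sum(res$percent_variance), 100, tolerance = 1e-6)
  expect_equal(crossprod(res$loadings), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # SVD oracle on the standardised matrix (up to axis sign)
  Z <- scale(X)
  sv <- svd(Z)
  sc_oracle <- sv$u %*% diag(sv$d)
  for (j in 1:6)
    expect_equal(abs(res$scores[, j]), abs(sc_oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)

  # supplementary row equal to a training row scores identically
  res2 <- pca_correlation(X, supplementary = X[c(3, 7), ])
  expect_equal(res2$supplementary_scores, res2$scores[c(3, 7), ],
               tolerance = 1e-10, ignore_attr = TRUE)
  # supplementary rows do not change the training fit
  expect_equal(res2$scores, res$scores, tolerance = 1e-12)

  # two perfectly correlated columns -> PC1 explains 100%
  X2 <- cbind(a = rnorm(20))
  X2 <- cbind(X2, b = 2 * X2[, 1] + 3)
  expect_equal(pca_correlation(X2)$percent_variance[1], 100,
               tolerance = 1e-8)

  Xz <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(pca_correlation(Xz), "zero-variance.*b")
})

test_that("percent variance is invariant to per-column affine rescaling", {
  set.seed(12)
  X <- matrix(rnorm(120), 30, 4)
  X2 <- sweep(sweep(X, 2, c(2, 5, 0.1, 7), "*"), 2, c(1, -3, 0, 10), "+")
  expect_equal(pca_correlation(X2)$percent_variance,
               pca_correlation(X)$percent_variance, tolerance = 1e-9)
})

test_that("lda separates groups and produces proper posteriors", {
  set.seed(13)
  X <- matrix(rnorm(400), 100, 4)
  grp <- rep(c("A", "B"), each = 50)
  X[grp == "B", 1] <- X[grp == "B", 1] + 10
  res <- lda_shared(X, grp, supplementary = X[1:5, , drop = FALSE])
  expect_equal(mean(res$predicted == grp), 1)
  expect_true(all(res$posterior[cbind(seq_len(100), as.integer(factor(grp)))]
                  > 0.999))
  expect_equal(unname(rowSums(res$posterior)), rep(1, 100), tolerance = 1e-9)
  expect_equal(unname(rowSums(res$supplementary_posterior)), rep(1, 5),
               tolerance = 1e-9)

  # symmetric two-group midpoint sample -> posterior 0.5/0.5 at equal priors
  Xs <- rbind(matrix(rnorm(100, -3), 50, 2), matrix(rnorm(100, 3), 50, 2))
  gs <- rep(c("L", "R"), each = 50)
  mid <- matrix(colMeans(rbind(colMeans(Xs[gs == "L", ]),
                               colMeans(Xs[gs == "R", ]))), 1)
  rs <- lda_shared(Xs, gs, priors = "uniform", supplementary = mid)
  expect_equal(unname(rs$supplementary_posterior[1, ]), c(0.5, 0.5),
               tolerance = 0.02)

  expect_error(lda_shared(X[1:51, ], c(rep("A", 50), "B")), "singleton.*B")
})

test_that("singular pooled covariance falls back to ridge with a warning", {
  set.seed(14)
  X <- matrix(rnorm(40), 10, 4)
  X <- cbind(X, X[, 1] + X[, 2])          # exactly collinear column
  grp <- rep(c("A", "B"), each = 5)
  expect_warning(res <- lda_shared(X, grp), "ridge")
  expect_true(res$ridge_used)
  expect_equal(unname(rowSums(res$posterior)), rep(1, 10), tolerance = 1e-9)
})

test_that("dapc with all PCs reproduces lda predictions", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(30:60, 1); p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    grp <- sample(c("A", "B", "C"), n, replace = TRUE)
    while (min(table(grp)) < 2) grp <- sample(c("A", "B", "C"), n,
                                              replace = TRUE)
    X[grp == "B", 1] <- X[grp == "B", 1] + 2
    X[grp == "C", 2] <- X[grp == "C", 2] - 2
    full <- dapc(X, grp, n_pcs = p)
    plain <- lda_shared(scale(X), grp)
    expect_equal(as.character(full$predicted), as.character(plain$predicted))
  }
})

test_that("dapc defaults, supplementary chain and rank guard work", {
  set.seed(16)
  X <- matrix(rnorm(200), 50, 4)
  grp <- rep(c("A", "B"), 25)
  X[grp == "B", ] <- X[grp == "B", ] + 3
  res <- dapc(X, grp, supplementary = X[1:3, , drop = FALSE])
  expect_true(res$n_pcs >= 1 && res$n_pcs <= 4)
  expect_equal(unname(rowSums(res$supplementary_posterior)), rep(1, 3),
               tolerance = 1e-9)
  expect_error(dapc(X, grp, n_pcs = 10), "rank")
})

test_that("cohen_kappa behaves at its landmarks", {
  lab <- rep(c("x", "y", "z"), 10)
  expect_equal(cohen_kappa(lab, lab)$kappa, 1)

  set.seed(17)
  a <- sample(c("p", "q"), 10000, replace = TRUE)
  b <- sample(c("p", "q"), 10000, replace = TRUE)
  k <- cohen_kappa(a, b)$kappa
  expect_gt(k, -0.05); expect_lt(k, 0.05)

  # constant rater: p_o equals p_e, kappa 0
  k2 <- cohen_kappa(rep("p", 100), sample(c("p", "q"), 100, replace = TRUE))
  expect_equal(k2$observed, k2$expected, tolerance = 1e-12)
  expect_equal(k2$kappa, 0, tolerance = 1e-9)

  expect_error(cohen_kappa(character(0), character(0)), "empty")
  expect_error(cohen_kappa(c("a", "b"), "a"), "length")
})

test_that("well-separated synthetic guilds reclassify with kappa >= 0.95", {
  set.seed(18)
  X <- rbind(matrix(rnorm(150, 0), 50, 3), matrix(rnorm(150, 6), 50, 3),
             matrix(rnorm(150, -6), 50, 3))
  grp <- rep(c("A", "B", "C"), each = 50)
  res <- lda_shared(X, grp)
  expect_gte(cohen_kappa(grp, res$predicted)$kappa, 0.95)
})
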