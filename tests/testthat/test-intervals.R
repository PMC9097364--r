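field <- function(strain, area = rep(1, length(strain)), label = "m") {
  structure(list(strain = strain, area = area, label = label),
            class = "strain_field")
}

test_that("mwam is the area-weighted mean", {
  expect_equal(mwam(field(c(100, 200, 300))), 200)
  expect_equal(mwam(field(c(100, 200), area = c(1, 3))), 175)
  set.seed(4)
  s <- runif(500, 0, 1000); a <- runif(500, 0.1, 2)
  naive <- 0; tot <- 0
  for (i in seq_along(s)) { naive <- naive + s[i] * a[i]; tot <- tot + a[i] }
  expect_equal(mwam(field(s, a)), naive / tot, tolerance = 1e-12)
  expect_gte(mwam(field(s, a)), min(s))
  expect_lte(mwam(field(s, a)), max(s))
  expect_error(mwam(field(numeric(0), numeric(0))), "empty")
})

test_that("interval_profile matches an area-weighted histogram", {
  p1 <- interval_profile(field(150), 4, c(0, 400))
  expect_equal(p1$percent, c(0, 100, 0, 0))

  p2 <- interval_profile(field(c(0, 400)), 4, c(0, 400))
  expect_equal(p2$percent, c(50, 0, 0, 50))  # hi lands in last interval

  set.seed(6)
  s <- runif(1000, 0, 900); a <- runif(1000, 0.5, 1.5)
  p <- interval_profile(field(s, a), 75, c(0, 900))
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)
  # brute-force histogram oracle
  brk <- seq(0, 900, length.out = 76)
  k <- findInterval(s, brk, rightmost.closed = TRUE)
  expected <- vapply(1:75, function(i) sum(a[k == i]), numeric(1))
  expect_equal(p$percent, 100 * expected / sum(a), tolerance = 1e-9)

  expect_error(interval_profile(field(1000), 10, c(0, 900)), "outside")
  expect_error(interval_profile(field(10), 1, c(0, 900)), "2 intervals")
})

test_that("impute_zeros preserves closure and respects detection limits", {
  M <- rbind(a = c(10, 20, 30, 40), b = c(25, 25, 25, 25))
  expect_equal(impute_zeros(M)$matrix, M)   # no zeros: identity

  set.seed(8)
  for (i in 1:100) {
    n <- sample(4:10, 1); d <- sample(3:8, 1)
    R <- matrix(rexp(n * d), n, d)
    R[sample(length(R), floor(length(R) * 0.2))] <- 0
    keep <- rowSums(R) > 0 & apply(R, 1, function(r) sum(r > 0) >= 2)
    R <- R[keep, , drop = FALSE]
    if (nrow(R) < 2) next
    R <- 100 * R / rowSums(R)
    nonzero_cols <- colSums(R > 0) > 0
    imp <- suppressWarnings(impute_zeros(R))
    expect_equal(unname(rowSums(imp$matrix)), rep(100, nrow(imp$matrix)),
                 tolerance = 1e-9)
    expect_true(all(imp$matrix > 0))
    if (nrow(imp$record)) {
      for (r in seq_len(nrow(imp$record)))
        expect_lt(imp$record$value[r], imp$record$detection_limit[r])
    }
  }

  Mz <- cbind(c(50, 60), c(50, 40), c(0, 0))
  Mz <- 100 * Mz / rowSums(Mz)
  expect_warning(res <- impute_zeros(Mz), "all-zero")
  expect_equal(res$dropped, 3L, ignore_attr = TRUE)
})

test_that("clr and ilr satisfy their algebraic identities", {
  u <- rep(100 / 3, 3)
  expect_equal(clr(u), rep(0, 3))
  expect_equal(ilr(u), rep(0, 2))

  expect_equal(ilr(c(exp(1) * 5, 5)), sqrt(1 / 2), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:25) {
    x <- rexp(sample(3:10, 1)) + 0.01
    expect_equal(sum(clr(x)), 0, tolerance = 1e-9)
    expect_equal(clr(3.7 * x), clr(x), tolerance = 1e-10)  # scale invariance
  }
  # isometry: ilr distances equal clr (Aitchison) distances
  X <- matrix(rexp(60) + 0.01, 10, 6)
  expect_equal(as.vector(dist(ilr(X))), as.vector(dist(clr(X))),
               tolerance = 1e-10)

  expect_error(clr(c(1, 0, 2)), "positive")
  expect_error(ilr(c(1, -1, 2)), "positive")
})

test_that("transform_profiles is deterministic and records imputation", {
  M <- rbind(m1 = c(60, 40, 0, 0), m2 = c(10, 30, 40, 20),
             m3 = c(0, 50, 30, 20))
  t1 <- transform_profiles(M, "ilr")
  t2 <- transform_profiles(M, "ilr")
  expect_identical(t1, t2)
  expect_equal(ncol(t1$coordinates), 3)      # D - 1
  expect_gt(nrow(t1$imputation), 0)
  tc <- transform_profiles(M, "clr")
  expect_equal(unname(rowSums(tc$coordinates)), rep(0, 3), tolerance = 1e-9)
})

test_that("converge_intervals picks a stable count on clustered fields", {
  set.seed(10)
  strong <- lapply(1:4, function(i)
    field(rgamma(300, shape = 4, scale = 30), runif(300, 0.5, 1.5),
          paste0("s", i)))
  weak <- lapply(1:4, function(i)
    field(rgamma(300, shape = 4, scale = 90), runif(300, 0.5, 1.5),
          paste0("w", i)))
  res <- suppressWarnings(
    converge_intervals(c(strong, weak), candidates = c(10, 25, 50, 75, 100)))
  expect_true(res$converged)
  expect_true(res$chosen %in% c(10, 25, 50, 75, 100))
  # cluster separation preserved at the chosen count
  rng <- c(0, max(vapply(c(strong, weak), function(f) max(f$strain),
                         numeric(1))))
  M <- profile_matrix(lapply(c(strong, weak), interval_profile,
                             n = res$chosen, range = rng))
  co <- suppressWarnings(transform_profiles(M, "ilr"))$coordinates
  d <- as.matrix(dist(co))
  within <- mean(c(d[1:4, 1:4][upper.tri(diag(4))],
                   d[5:8, 5:8][upper.tri(diag(4))]))
  between <- mean(d[1:4, 5:8])
  expect_gt(between, within)

  # identical profiles at every count -> smallest candidate
  same <- lapply(1:3, function(i) field(c(100, 500), c(1, 1), paste0("x", i)))
  res2 <- suppressWarnings(converge_intervals(same, candidates = c(5, 10, 20)))
  expect_equal(res2$chosen, 5L)
})
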