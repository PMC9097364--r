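# Phylogenetic signal statistics and the permutation pairwise test.
#
# K compares observed trait similarity among relatives to the similarity
# expected under Brownian motion on the tree; K = 1 under Brownian motion,
# K < 1 means relatives are less similar than expected, K > 1 more similar.
# The multivariate form sums squared deviations across trait columns in both
# the raw-space numerator and the C^-1-weighted denominator, and reduces
# exactly to K for a single column.

# inverse square-root factor of C by eigendecomposition, eigenvalue floor
# guards against ill-conditioning introduced by fossil grafting (0.01 Ma
# divergences make near-identical rows).
cov_inv_sqrt <- function(C, floor = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(v))
}

k_statistic <- function(C, Y) {
  Y <- as.matrix(Y)
  N <- nrow(C)
  Cinv <- solve(C)
  one <- rep(1, N)
  denom1 <- drop(crossprod(one, Cinv %*% one))
  a <- drop(crossprod(one, Cinv %*% Y)) / denom1     # phylogenetic mean per column
  Dev <- sweep(Y, 2L, a)                             # deviations from root state
  mse0 <- sum(Dev * Dev)                             # raw-space sum of squares
  mse  <- sum(Dev * (Cinv %*% Dev))                  # C^-1 weighted
  expected <- (sum(diag(C)) - N / denom1) / (N - 1)
  (mse0 / mse) / expected
}

signal_result <- function(statistic, p, nperm, seed, type) {
  structure(list(statistic = statistic, p = p, nperm = nperm, seed = seed,
                 type = type),
            class = "signal_result")
}

#' @exportS3Method base::print
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  (p = %.4g, %d permutations)\n",
              x$type, x$statistic, x$p, x$nperm))
  invisible(x)
}

signal_test <- function(tree, Y, nperm, seed, type) {
  Y <- as.matrix(Y)
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips")
  if (is.null(rownames(Y))) rownames(Y) <- tree$tip.label
  Y <- Y[tree$tip.label, , drop = FALSE]
  if (any(apply(Y, 2L, stats::sd) == 0))
    stop("degenerate input: constant trait column")
  C <- phylo_vcv(tree)
  obs <- k_statistic(C, Y)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(Y)
  count <- 0L
  for (i in seq_len(nperm)) {
    # tip shuffling: permute trait rows across tips
    if (k_statistic(C, Y[sample.int(N), , drop = FALSE]) >= obs)
      count <- count + 1L
  }
  signal_result(obs, (count + 1) / (nperm + 1), nperm, seed, type)
}

#' Blomberg's K for a univariate trait
#'
#' K = (MSE0/MSE) / E\[MSE0/MSE\] where MSE0 is the mean squared deviation of
#' the trait from its phylogenetic (GLS) mean in raw space, MSE the
#' C^-1-weighted form, and the expectation term (tr(C) - N/(1'C^-1 1))/(N-1)
#' is the ratio expected under Brownian motion.  Significance is assessed by
#' shuffling trait values across tips; the reported p has +1 smoothing so its
#' floor is 1/(nperm+1).
#'
#' @param tree `phylo` with >= 4 tips.
#' @param y Named numeric vector (names = tip labels) or aligned to tip order.
#' @param nperm Number of permutations.
#' @param seed Integer seed (optional).
#' @return A `signal_result`: statistic, p, nperm, seed.
#' @export
blomberg_k <- function(tree, y, nperm = 999, seed = NULL) {
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1,
                                       dimnames = list(names(y), NULL))
  if (ncol(y) != 1L) stop("blomberg_k is univariate; use k_mult")
  signal_test(tree, y, nperm, seed, "K")
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' Generalises Blomberg's K by summing squared deviations across trait
#' columns in the numerator and their C^-1-weighted counterparts in the
#' denominator.  For one column the statistic equals K exactly.
#'
#' @inheritParams blomberg_k
#' @param Y Numeric matrix, rows = tips (rownames = tip labels).
#' @return A `signal_result`.
#' @export
k_mult <- function(tree, Y, nperm = 999, seed = NULL) {
  signal_test(tree, as.matrix(Y), nperm, seed, "K_mult")
}

#' Permutation-based pairwise comparison of group means under a phylogenetic
#' covariance ("phylogenetic HSD")
#'
#' Trait data are transformed by an inverse square-root factor of the
#' Brownian covariance C, group least-squares means are computed in the
#' transformed space, and observed pairwise Euclidean distances between
#' group means are compared against a null distribution generated by
#' randomising the residuals of the reduced (intercept-only) model and
#' refitting (residual-randomisation permutation procedure).  Mimics Tukey's
#' HSD over many groups while correcting for phylogenetic non-independence.
#'
#' @param tree `phylo`.
#' @param Y Trait matrix (rownames = tip labels) or vector.
#' @param groups Factor or character vector of group labels, aligned to Y
#'   rows (or named by taxon).
#' @param nperm Permutations (1000 by convention).
#' @param seed Integer seed.
#' @return A `pairwise_result` with `p` (symmetric matrix of smoothed
#'   p-values), `distance` (observed between-mean distances), `nperm`,
#'   `seed`.
#' @export
phylo_hsd <- function(tree, Y, groups, nperm = 1000, seed = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) rownames(Y) <- tree$tip.label
  Y <- Y[tree$tip.label, , drop = FALSE]
  if (!is.null(names(groups))) groups <- groups[tree$tip.label]
  groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         " (single-member categories must be removed before testing)")
  C <- phylo_vcv(tree)
  P <- cov_inv_sqrt(C)
  Yt <- P %*% Y
  X  <- stats::model.matrix(~ groups - 1)          # cell-means coding
  Xt <- P %*% X
  one_t <- P %*% rep(1, nrow(Y))                   # transformed intercept
  # full-model projector onto group means (transformed space)
  A_full <- solve(crossprod(Xt), t(Xt))
  # reduced (intercept-only) fit
  A_red  <- solve(crossprod(one_t), t(one_t))
  coef_red <- A_red %*% Yt
  fit_red  <- one_t %*% coef_red
  res_red  <- Yt - fit_red
  G <- nlevels(groups)
  pair <- utils::combn(G, 2L)
  dist_between <- function(M) {                    # M: G x p group means
    d <- numeric(ncol(pair))
    for (k in seq_len(ncol(pair)))
      d[k] <- sqrt(sum((M[pair[1L, k], ] - M[pair[2L, k], ])^2))
    d
  }
  obs <- dist_between(A_full %*% Yt)
  if (!is.null(seed)) set.seed(seed)
  count <- integer(length(obs))
  n <- nrow(Yt)
  for (i in seq_len(nperm)) {
    Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
    count <- count + (dist_between(A_full %*% Yp) >= obs)
  }
  p <- (count + 1) / (nperm + 1)
  lev <- levels(groups)
  Pm <- matrix(NA_real_, G, G, dimnames = list(lev, lev))
  Dm <- matrix(0, G, G, dimnames = list(lev, lev))
  diag(Pm) <- 1
  for (k in seq_len(ncol(pair))) {
    i <- pair[1L, k]; j <- pair[2L, k]
    Pm[i, j] <- Pm[j, i] <- p[k]
    Dm[i, j] <- Dm[j, i] <- obs[k]
  }
  structure(list(p = Pm, distance = Dm, nperm = nperm, seed = seed),
            class = "pairwise_result")
}

#' @exportS3Method base::print
print.pairwise_result <- function(x, ...) {
  cat(sprintf("pairwise permutation test (%d permutations)\np-values:\n", x$nperm))
  print(round(x$p, 4))
  invisible(x)
}
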