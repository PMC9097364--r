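# Ordination and discriminant machinery.  Fossil specimens never influence
# the fit: they are standardised by the training centering/scaling and
# projected through the training rotation ("supplementary" rows), so extant
# structure is estimated from extant taxa only.

#' Correlation-matrix PCA with supplementary projection
#'
#' Principal components of the correlation matrix of the training rows
#' (inputs scaled to unit variance, removing units).  Supplementary (e.g.
#' fossil) rows are standardised by the training mean/sd and rotated; they
#' have no effect on the fit.
#'
#' @param X Numeric training matrix (rows = taxa).
#' @param supplementary Optional matrix of supplementary rows (same
#'   columns).
#' @return Object of class `ordination_result`: `scores`, `loadings`
#'   (orthonormal columns), `percent_variance`, `center`, `scale`,
#'   `supplementary_scores`.
#' @export
pca_correlation <- function(X, supplementary = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero <- scl == 0
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(X)[zero] %||% which(zero), collapse = ", "))
  Z <- scale(X, center = ctr, scale = scl)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  # deterministic sign: largest-magnitude loading positive per axis
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- Z %*% V
  supp <- if (!is.null(supplementary)) {
    S <- as.matrix(supplementary)[, colnames(X) %||% seq_len(ncol(X)),
                                  drop = FALSE]
    scale(S, center = ctr, scale = scl) %*% V
  }
  structure(list(scores = scores, loadings = V,
                 percent_variance = 100 * ev / sum(ev),
                 center = ctr, scale = scl,
                 supplementary_scores = supp),
            class = "ordination_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear discriminant analysis with shared covariance and supplementary
#' prediction
#'
#' Fisher discriminant axes from the W^-1 B eigenproblem (W pooled
#' within-group covariance, B between-group covariance) and Gaussian
#' posteriors under a shared covariance with the stated priors, for both
#' training and supplementary rows.  Singleton groups are rejected; a
#' singular W is regularised by a small ridge with a warning (log-ratio
#' interval data can have more columns than group members).
#'
#' @param X Numeric training matrix.
#' @param groups Group labels for training rows.
#' @param priors `"proportions"` (training class proportions, the default),
#'   `"uniform"`, or a named numeric vector summing to 1.
#' @param supplementary Optional matrix of unlabelled rows to predict.
#' @return Object of class `discriminant_result`: `axes` (variables x
#'   discriminants), `means`, `covariance`, `priors`, `posterior`,
#'   `predicted`, `percent_between_variance`, `supplementary_posterior`,
#'   `supplementary_predicted`, plus the training `scores` and
#'   `supplementary_scores` on the discriminant axes.
#' @export
lda_shared <- function(X, groups, priors = "proportions",
                       supplementary = NULL) {
  X <- as.matrix(X)
  groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  G <- nlevels(groups); p <- ncol(X); n <- nrow(X)
  means <- apply(X, 2L, function(col) tapply(col, groups, mean))
  means <- matrix(means, nrow = G,
                  dimnames = list(levels(groups), colnames(X)))
  W <- matrix(0, p, p)
  for (g in levels(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2L, means[g, ]))
  }
  W <- W / (n - G)
  ridge_used <- FALSE
  Winv <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Winv) || !all(is.finite(Winv)) || kappa(W) > 1e12) {
    lambda <- 1e-8 * sum(diag(W)) / p
    W <- W + diag(lambda, p)
    Winv <- solve(W)
    ridge_used <- TRUE
    warning("singular pooled covariance; ridge regularisation applied")
  }
  grand <- colMeans(X)
  B <- matrix(0, p, p)
  for (g in levels(groups)) {
    d <- means[g, ] - grand
    B <- B + sizes[[g]] * tcrossprod(d)
  }
  B <- B / (n - 1)
  ed <- eigen(Winv %*% B)
  naxes <- min(G - 1L, p)
  ord <- order(Re(ed$values), decreasing = TRUE)[seq_len(naxes)]
  axes <- Re(ed$vectors[, ord, drop = FALSE])
  for (j in seq_len(ncol(axes))) {                  # reproducible sign
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  rownames(axes) <- colnames(X)
  colnames(axes) <- paste0("LD", seq_len(naxes))
  evals <- Re(ed$values[ord])
  pr <- if (identical(priors, "proportions")) as.numeric(sizes) / n
        else if (identical(priors, "uniform")) rep(1 / G, G)
        else as.numeric(priors[levels(groups)])
  names(pr) <- levels(groups)
  if (abs(sum(pr) - 1) > 1e-8) stop("priors must sum to 1")
  post_fun <- function(M) {
    # log density under N(mean_g, W) + log prior, stabilised softmax
    lp <- matrix(0, nrow(M), G, dimnames = list(rownames(M), levels(groups)))
    for (gi in seq_len(G)) {
      D <- sweep(M, 2L, means[gi, ])
      lp[, gi] <- -0.5 * rowSums((D %*% Winv) * D) + log(pr[gi])
    }
    mx <- apply(lp, 1L, max)
    el <- exp(lp - mx)
    el / rowSums(el)
  }
  post <- post_fun(X)
  res <- list(axes = axes, means = means, covariance = W, priors = pr,
              posterior = post,
              predicted = factor(levels(groups)[max.col(post)],
                                 levels = levels(groups)),
              percent_between_variance = 100 * evals / sum(evals),
              scores = X %*% axes,
              ridge_used = ridge_used,
              supplementary_posterior = NULL,
              supplementary_predicted = NULL,
              supplementary_scores = NULL)
  if (!is.null(supplementary)) {
    S <- as.matrix(supplementary)
    sp <- post_fun(S)
    res$supplementary_posterior <- sp
    res$supplementary_predicted <- factor(levels(groups)[max.col(sp)],
                                          levels = levels(groups))
    res$supplementary_scores <- S %*% axes
  }
  structure(res, class = "discriminant_result")
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Correlation-matrix PCA de-correlates the variables, then LDA is run on
#' the first `n_pcs` principal-component scores; supplementary rows pass
#' through the same standardisation, rotation and discriminant chain.
#' With all PCs retained the predictions coincide with plain LDA on the
#' standardised data.
#'
#' @inheritParams lda_shared
#' @param n_pcs Number of PCs fed to the LDA; default the smallest number
#'   explaining `var_target` of the variance.
#' @param var_target Fraction of variance the default `n_pcs` must reach.
#' @return A `discriminant_result` (see [lda_shared()]) with an added
#'   `pca` element and `n_pcs`.
#' @export
dapc <- function(X, groups, n_pcs = NULL, priors = "proportions",
                 supplementary = NULL, var_target = 0.99) {
  pca <- pca_correlation(X, supplementary = supplementary)
  if (is.null(n_pcs)) {
    cum <- cumsum(pca$percent_variance) / 100
    n_pcs <- which(cum >= var_target)[1L]
  }
  if (n_pcs > ncol(pca$scores)) stop("n_pcs exceeds the rank of X")
  res <- lda_shared(pca$scores[, seq_len(n_pcs), drop = FALSE], groups,
                    priors = priors,
                    supplementary = if (!is.null(supplementary))
                      pca$supplementary_scores[, seq_len(n_pcs), drop = FALSE])
  res$pca <- pca
  res$n_pcs <- n_pcs
  res
}

#' Two-rater agreement kappa
#'
#' kappa = (p_o - p_e)/(1 - p_e) with expected agreement p_e from the
#' product of the two raters' marginal label frequencies (the two-rater,
#' i.e. Cohen, form; used here to compare an a priori classification with
#' discriminant predictions).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return Object of class `agreement_result`: `kappa`, `observed`,
#'   `expected`, `table` (confusion matrix).
#' @export
cohen_kappa <- function(true_labels, predicted_labels) {
  if (!length(true_labels)) stop("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop("label sequences differ in length")
  lev <- union(as.character(true_labels), as.character(predicted_labels))
  a <- factor(true_labels, levels = lev)
  b <- factor(predicted_labels, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  k <- if (abs(1 - pe) < .Machine$double.eps) {
    if (po == 1) 1 else 0
  } else (po - pe) / (1 - pe)
  structure(list(kappa = k, observed = po, expected = pe, table = tab),
            class = "agreement_result")
}
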