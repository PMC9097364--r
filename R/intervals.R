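# The intervals method: summarise an FE strain field as the percent of
# model area falling in each of n equal strain intervals over a range
# shared by all compared models, then treat the profiles as compositional
# data (zero imputation, log-ratio transforms) before ordination.

#' Mesh-weighted arithmetic mean strain
#'
#' MWAM = sum(strain_e * area_e) / sum(area_e): the element-area-weighted
#' mean of the per-element failure-criterion values.
#'
#' @param f A [strain_field()].
#' @return Microstrain.
#' @export
mwam <- function(f) {
  if (!length(f$strain)) stop("empty strain field")
  sum(f$strain * f$area) / sum(f$area)
}

#' Percent model area per strain interval
#'
#' Splits `[lo, hi]` into `n` equal intervals, interval k being
#' `[lo + k w, lo + (k+1) w)` with the last interval closed, and returns the
#' percent of total model area whose element strain falls in each.  The
#' range must cover every strain in the comparison set (compute a global
#' range first).
#'
#' @param f A [strain_field()].
#' @param n Number of intervals (>= 2).
#' @param range Numeric length-2 `c(lo, hi)` shared by all compared models.
#' @return Object of class `strain_profile`: `percent` (sums to 100),
#'   `n_intervals`, `range`, `label`.
#' @export
interval_profile <- function(f, n, range) {
  if (n < 2L) stop("need at least 2 intervals")
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) stop("range must have hi > lo")
  if (any(f$strain < lo | f$strain > hi))
    stop("strain outside the stated range; compute a global range over all ",
         "models first")
  w <- (hi - lo) / n
  k <- pmin(floor((f$strain - lo) / w), n - 1L)   # values at hi -> last interval
  pct <- vapply(seq_len(n) - 1L,
                function(i) sum(f$area[k == i]), numeric(1))
  pct <- 100 * pct / sum(f$area)
  structure(list(percent = pct, n_intervals = as.integer(n),
                 range = c(lo, hi), label = f$label),
            class = "strain_profile")
}

#' Stack strain profiles into a model x interval matrix
#' @param profiles List of `strain_profile`s sharing n and range.
#' @return Matrix with model labels as rownames; rows sum to 100.
#' @export
profile_matrix <- function(profiles) {
  n <- unique(vapply(profiles, function(p) p$n_intervals, integer(1)))
  if (length(n) != 1L) stop("profiles disagree on interval count")
  M <- do.call(rbind, lapply(profiles, function(p) p$percent))
  rownames(M) <- vapply(profiles, function(p) p$label, character(1))
  M
}

# mean of a lognormal(mu, sigma) truncated above at dl (closed form); this
# is always < dl and > 0
truncated_lognormal_mean <- function(mu, sigma, dl) {
  if (sigma <= 0) return(min(dl * 0.65, exp(mu)))  # degenerate column: fallback
  z <- (log(dl) - mu) / sigma
  denom <- stats::pnorm(z)
  if (denom <= 0) return(dl * 0.65)
  ev <- exp(mu + sigma^2 / 2) * stats::pnorm(z - sigma) / denom
  min(ev, dl * (1 - 1e-12))
}

#' Impute zeros in a compositional profile matrix
#'
#' Zeros in each column are replaced by the expected value of a lognormal
#' fitted (method of moments on the log of the nonzero entries) to that
#' column, truncated above at the column detection limit (its smallest
#' observed nonzero), so every imputed value is strictly positive and below
#' the detection limit.  Nonzero entries of affected rows are then
#' multiplicatively rescaled so each row still sums to 100.  Columns that
#' are entirely zero are dropped with a warning.
#'
#' @param M Matrix of percent compositions (rows sum to 100).
#' @return List of class `imputed_profiles`: `matrix` (strictly positive,
#'   rows sum to 100), `record` (data frame of imputed cells), `dropped`
#'   (indices of all-zero columns removed).
#' @export
impute_zeros <- function(M) {
  M <- as.matrix(M)
  all_zero <- colSums(M > 0) == 0L
  dropped <- which(all_zero)
  if (length(dropped)) {
    warning(length(dropped), " all-zero column(s) dropped")
    M <- M[, !all_zero, drop = FALSE]
  }
  rec <- list()
  out <- M
  for (j in seq_len(ncol(M))) {
    nz <- M[, j] > 0
    if (all(nz)) next
    vals <- M[nz, j]
    dl <- min(vals)
    lx <- log(vals)
    imp <- truncated_lognormal_mean(mean(lx),
                                    if (length(lx) > 1L) stats::sd(lx) else 0,
                                    dl)
    out[!nz, j] <- imp
    rec[[length(rec) + 1L]] <- data.frame(row = which(!nz), column = j,
                                          value = imp,
                                          detection_limit = dl)
  }
  # multiplicative closure: scale original nonzeros so rows sum to 100 again
  for (i in seq_len(nrow(out))) {
    zero_mask <- M[i, ] == 0
    if (!any(zero_mask)) next
    imputed_sum <- sum(out[i, zero_mask])
    out[i, !zero_mask] <- out[i, !zero_mask] *
      (100 - imputed_sum) / sum(M[i, !zero_mask])
  }
  structure(list(matrix = out,
                 record = if (length(rec)) do.call(rbind, rec)
                          else data.frame(row = integer(0), column = integer(0),
                                          value = numeric(0),
                                          detection_limit = numeric(0)),
                 dropped = dropped),
            class = "imputed_profiles")
}

#' Centred log-ratio transform
#'
#' clr(x)_i = ln(x_i / g(x)) with g the geometric mean; output sums to 0 and
#' is invariant to rescaling of the row.  Used for interpreting
#' character weightings.
#'
#' @param x Strictly positive composition (vector) or matrix (row-wise).
#' @return Same shape as input.
#' @export
clr <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(apply(x, 1L, clr), nrow = nrow(x), byrow = TRUE)
    rownames(out) <- rownames(x)
    return(out)
  }
  if (any(x <= 0)) stop("clr requires strictly positive components")
  log(x) - mean(log(x))
}

#' Isometric log-ratio transform (pivot basis)
#'
#' ilr_i = sqrt(i/(i+1)) * ln(g(x_1..x_i) / x_{i+1}), i = 1..D-1: the
#' sequential-binary-partition pivot basis.  Distances between ilr rows
#' equal Aitchison (clr) distances; the analysis matrix for ordination.
#'
#' @param x Strictly positive composition (vector) or matrix (row-wise).
#' @return Length D-1 vector (or matrix with D-1 columns).
#' @export
ilr <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(apply(x, 1L, ilr), nrow = nrow(x), byrow = TRUE)
    rownames(out) <- rownames(x)
    return(out)
  }
  if (any(x <= 0)) stop("ilr requires strictly positive components")
  D <- length(x)
  lx <- log(x)
  cums <- cumsum(lx)
  i <- seq_len(D - 1L)
  sqrt(i / (i + 1)) * (cums[i] / i - lx[i + 1L])
}

#' Transform a profile matrix for multivariate analysis
#'
#' Runs zero imputation then the chosen log-ratio transform, recording the
#' imputation and the basis.
#'
#' @param M Percent composition matrix (rows sum to 100).
#' @param transform `"ilr"` (analysis; default) or `"clr"` (weight
#'   interpretation).
#' @return List of class `transformed_profiles`: `coordinates`, `transform`,
#'   `imputation` record, `dropped` columns.
#' @export
transform_profiles <- function(M, transform = c("ilr", "clr")) {
  transform <- match.arg(transform)
  imp <- impute_zeros(M)
  coords <- if (transform == "ilr") ilr(imp$matrix) else clr(imp$matrix)
  rownames(coords) <- rownames(imp$matrix)
  structure(list(coordinates = coords, transform = transform,
                 imputation = imp$record, dropped = imp$dropped),
            class = "transformed_profiles")
}

#' Choose a stable interval count by convergence testing
#'
#' For consecutive candidate interval counts, builds profiles, imputes,
#' ilr-transforms and computes inter-model distance matrices; the chosen
#' count is the smallest whose distance-matrix correlation with the next
#' candidate is at least `1 - tol`.  If none converges the largest
#' candidate is returned with a warning.
#'
#' @param fields List of [strain_field()]s (the comparison set).
#' @param candidates Ascending integer interval counts.
#' @param tol Convergence tolerance on the correlation (default 0.01).
#' @return List of class `interval_convergence`: `chosen`, `correlations`
#'   (named by "n1->n2"), `converged`.
#' @export
converge_intervals <- function(fields, candidates = c(10, 25, 50, 75, 100),
                               tol = 0.01) {
  if (length(candidates) < 2L) stop("need at least 2 candidate counts")
  candidates <- sort(as.integer(candidates))
  rng <- c(0, max(vapply(fields, function(f) max(f$strain), numeric(1))))
  dist_at <- function(n) {
    M <- profile_matrix(lapply(fields, interval_profile, n = n, range = rng))
    as.vector(stats::dist(transform_profiles(M, "ilr")$coordinates))
  }
  dmats <- lapply(candidates, dist_at)
  # degenerate (constant) distance vectors have no product-moment
  # correlation; treat exact agreement as perfect concordance
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(if (max(abs(a - b)) < 1e-9) 1 else 0)
    stats::cor(a, b)
  }
  cors <- vapply(seq_len(length(candidates) - 1L), function(k)
    safe_cor(dmats[[k]], dmats[[k + 1L]]), numeric(1))
  names(cors) <- paste0(candidates[-length(candidates)], "->", candidates[-1L])
  ok <- cors >= 1 - tol
  if (any(diff(cors) < -1e-6))
    warning("convergence diagnostic is not monotone non-decreasing")
  if (any(ok)) {
    chosen <- candidates[which(ok)[1L]]
    converged <- TRUE
  } else {
    warning("no interval count converged; returning the largest candidate")
    chosen <- candidates[length(candidates)]
    converged <- FALSE
  }
  structure(list(chosen = chosen, correlations = cors, converged = converged),
            class = "interval_convergence")
}
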