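# Body-mass estimation for fossil enantiornithines and mass-based dietary
# exclusion rules.
#
# The multivariate regression (six log10 skeletal predictors) gives a log10
# point estimate; the published interval machinery of the source regression
# is not restated here, so interval half-width on the log10 scale is a
# caller-supplied stand-in calibrated so mean/lower ratios are about 1.25.

#' ENAN body-mass regression coefficients
#' @return Named numeric vector: intercept and the six predictor slopes.
#' @export
enan_coefficients <- function() {
  c(intercept = -2.626, HL = 1.528, bcL = 0.34, dHW = 0.828,
    UL = -1.451, dUW = 0.811, TL = 0.378)
}

#' Estimate body mass from skeletal measurements (ENAN regression)
#'
#' Linear predictor on log10-transformed measurements:
#' -2.626 + 1.528 HL + 0.34 bcL + 0.828 dHW - 1.451 UL + 0.811 dUW
#' + 0.378 TL, back-transformed as correction x 10^lp and converted to
#' grams by `unit_to_g` (the fitted mass unit is configured explicitly, not
#' assumed).
#'
#' @param m Named list/vector with log10 measurements `HL` (humerus length),
#'   `bcL` (bicipital crest length), `dHW` (distal humerus width), `UL`
#'   (ulna length), `dUW` (distal ulna width), `TL` (tibiotarsus length).
#' @param correction Dimensionless correction factor (back-calculated from
#'   the source regression; approximately 1).
#' @param interval_halfwidth Symmetric half-width of the interval on the
#'   log10 scale; default log10(1.25) gives mean/lower of about 1.25.
#' @param unit_to_g Multiplier converting the fitted mass unit to grams.
#' @return List of class `mass_estimate`: `mean`, `lower`, `upper` (g).
#' @export
enan_mass <- function(m, correction = 1, interval_halfwidth = log10(1.25),
                      unit_to_g = 1) {
  coefs <- enan_coefficients()
  preds <- setdiff(names(coefs), "intercept")
  missing <- preds[!preds %in% names(m)]
  if (length(missing)) stop("missing predictors: ", paste(missing, collapse = ", "))
  vals <- vapply(preds, function(k) as.numeric(m[[k]]), numeric(1))
  if (any(!is.finite(vals))) stop("non-finite predictor value")
  lp <- coefs[["intercept"]] + sum(coefs[preds] * vals)
  mean_g <- correction * 10^lp * unit_to_g
  structure(list(mean = mean_g,
                 lower = correction * 10^(lp - interval_halfwidth) * unit_to_g,
                 upper = correction * 10^(lp + interval_halfwidth) * unit_to_g),
            class = "mass_estimate")
}

#' Aggregate published masses to one species mass
#'
#' Three aggregation rules, applied in the order the data allow: sex means
#' are averaged equally; subspecies/population means are averaged weighted
#' by their sample counts; a maximum/minimum pair is replaced by its
#' midpoint.
#'
#' @param values Numeric masses (g).
#' @param weights Optional sample counts for a weighted mean.
#' @param range_pair If `TRUE`, `values` is a max/min pair and the midpoint
#'   is returned.
#' @return Single mass (g).
#' @export
aggregate_mass <- function(values, weights = NULL, range_pair = FALSE) {
  if (range_pair) {
    if (length(values) != 2L) stop("range_pair expects exactly two values")
    return(mean(values))
  }
  if (is.null(weights)) mean(values) else stats::weighted.mean(values, weights)
}

#' Youden-index optimal cut-points between two guilds on log10 mass
#'
#' Evaluates J(t) = sensitivity(t) + specificity(t) - 1 at every midpoint
#' between consecutive distinct sorted log10 masses and returns all
#' maximising thresholds (multiple optima are reported, matching cases
#' where two cut-offs tie).  "Positive" is the larger-mean guild, so
#' sensitivity is the fraction of that guild above the threshold.
#'
#' @param masses_g Numeric masses in grams (positive).
#' @param labels Binary guild labels (factor/character/logical), same length.
#' @return List of class `cutpoint_result`: `thresholds_g` (ascending),
#'   `J`, `direction` (the guild below the threshold), `positive` (the
#'   guild treated as positive/above).
#' @export
youden_cutpoints <- function(masses_g, labels) {
  if (any(masses_g <= 0)) stop("masses must be positive")
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two guilds required; got ",
                                  nlevels(labels))
  x <- log10(masses_g)
  means <- tapply(x, labels, mean)
  positive <- names(means)[which.max(means)]   # larger-mass guild
  negative <- setdiff(levels(labels), positive)
  pos <- labels == positive
  xs <- sort(unique(x))
  if (length(xs) < 2L) stop("degenerate mass distribution")
  cand <- (xs[-1L] + xs[-length(xs)]) / 2
  J <- vapply(cand, function(t) {
    sens <- mean(x[pos] > t)
    spec <- mean(x[!pos] <= t)
    sens + spec - 1
  }, numeric(1))
  best <- max(J)
  th <- sort(cand[abs(J - best) < 1e-12])
  structure(list(thresholds_g = 10^th, J = best, direction = negative,
                 positive = positive),
            class = "cutpoint_result")
}

#' Diet categories excluded by a body-mass estimate
#'
#' Mass-threshold rules: masses of 300-450 g are indeterminate between
#' carnivore guilds and 250-400 g between herbivore guilds; outside those
#' bands, vertivory is excluded below (upper < 300 g) and invertivory above
#' (lower > 450 g); folivory/frugivory is excluded below (upper < 250 g)
#' and granivory/nectarivory above (lower > 400 g).  A range straddling a
#' band excludes nothing for that comparison.
#'
#' @param mass A `mass_estimate` (or list with `lower` and `upper` in g).
#' @return Character vector of excluded diet categories (possibly empty).
#' @export
mass_rule <- function(mass) {
  lower <- mass$lower; upper <- mass$upper
  excluded <- character(0)
  if (upper < 300) excluded <- c(excluded, vertivore_categories())
  if (lower > 450) excluded <- c(excluded, "InvertivoreH", "InvertivoreM",
                                 "InvertivoreS")
  if (upper < 250) excluded <- c(excluded, "Folivore", "FrugivoreH",
                                 "FrugivoreS")
  if (lower > 400) excluded <- c(excluded, "GranivoreH", "GranivoreS",
                                 "Nectarivore")
  unique(excluded)
}
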