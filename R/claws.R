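# Claw traditional morphometrics: outer-arc curvature (Oo) and outer-arc
# length (ALo) from three landmarks on the dorsal (outer) curve of the
# ungual -- the proximal point at the dorsal base of the extensor tubercle,
# a midpoint on the outer curve, and the claw tip.  The unique circle
# through the three points gives the arc; Oo is its central angle.

# circumcircle through three points; returns list(center, radius) or NULL if
# collinear beyond tolerance.
circumcircle <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
              p3[1] * (p1[2] - p2[2]))
  chord <- sqrt(sum((p3 - p1)^2))
  if (abs(d) < .Machine$double.eps * 100 * max(1, chord^2)) return(NULL)
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  ux <- (s1 * (p2[2] - p3[2]) + s2 * (p3[2] - p1[2]) + s3 * (p1[2] - p2[2])) / d
  uy <- (s1 * (p3[1] - p2[1]) + s2 * (p1[1] - p3[1]) + s3 * (p2[1] - p1[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((p1 - ctr)^2)))
}

#' Construct a claw landmark set
#'
#' @param digit One of `"DI"`, `"DII"`, `"DIII"`, `"DIV"`.
#' @param proximal,midpoint,tip Planar points (length-2 numeric, mm):
#'   dorsal base of the extensor tubercle, outer-curve midpoint, claw tip.
#' @return Object of class `claw_landmarks`.
#' @export
claw_landmarks <- function(digit, proximal, midpoint, tip) {
  digit <- match.arg(digit, c("DI", "DII", "DIII", "DIV"))
  pts <- rbind(proximal, midpoint, tip)
  if (any(duplicated(pts))) stop("claw landmarks must be pairwise distinct")
  structure(list(digit = digit, proximal = as.numeric(proximal),
                 midpoint = as.numeric(midpoint), tip = as.numeric(tip)),
            class = "claw_landmarks")
}

claw_circle <- function(c) {
  cc <- circumcircle(c$proximal, c$midpoint, c$tip)
  chord <- sqrt(sum((c$tip - c$proximal)^2))
  if (is.null(cc) || cc$radius > 1e6 * chord) return(NULL)  # pathologically straight
  cc
}

# central angle (radians, in (0, 2*pi)) of the arc from proximal to tip that
# passes through the midpoint
claw_angle_rad <- function(c) {
  cc <- claw_circle(c)
  if (is.null(cc)) {
    warning("near-collinear claw landmarks; curvature reported as 0")
    return(0)
  }
  ang <- function(p) atan2(p[2] - cc$center[2], p[1] - cc$center[1])
  a1 <- ang(c$proximal); am <- ang(c$midpoint); a3 <- ang(c$tip)
  ccw <- function(from, to) (to - from) %% (2 * pi)   # ccw sweep
  # does the ccw arc from proximal to tip contain the midpoint?
  if (ccw(a1, am) <= ccw(a1, a3)) ccw(a1, a3) else ccw(a3, a1)
}

#' Outer-arc curvature of a claw (degrees)
#'
#' Fits the unique circle through the three outer-curve landmarks and
#' returns the central angle of the arc from the proximal landmark to the
#' tip passing through the midpoint.  Near-collinear landmarks
#' (circumradius > 1e6 x chord) give 0 degrees with a warning: effectively
#' straight claws occur in ground birds.
#'
#' @param c A [claw_landmarks()] object.
#' @return Angle in degrees, in (0, 360).
#' @export
claw_curvature <- function(c) claw_angle_rad(c) * 180 / pi

#' Outer-arc length of a claw
#'
#' Arc length = radius x central angle on the fitted circle.
#'
#' @param c A [claw_landmarks()] object.
#' @return Arc length in the landmark units (mm).
#' @export
claw_arc_length <- function(c) {
  cc <- claw_circle(c)
  if (is.null(cc)) {
    warning("near-collinear claw landmarks; using chord length")
    return(sqrt(sum((c$tip - c$proximal)^2)))
  }
  cc$radius * claw_angle_rad(c)
}

#' Claw traditional-morphometric feature vector
#'
#' Curvature (Oo, degrees) for each of the four digits plus ratios of
#' outer-arc length of the three non-reference digits to the reference
#' digit (DIII or DIV).  Seven analysis variables per taxon.
#'
#' @param claws Named list of four [claw_landmarks()], names `DI`..`DIV`.
#' @param reference Reference digit, `"DIII"` (default) or `"DIV"`.
#' @return Named numeric vector: `Oo_DI..Oo_DIV`, `ALo_<digit>_ratio` for
#'   the non-reference digits; attribute `reference`.
#' @export
tm_features <- function(claws, reference = "DIII") {
  digits <- c("DI", "DII", "DIII", "DIV")
  reference <- match.arg(reference, digits)
  missing <- setdiff(digits, names(claws))
  if (length(missing)) stop("missing digits: ", paste(missing, collapse = ", "))
  oo <- vapply(claws[digits], claw_curvature, numeric(1))
  al <- vapply(claws[digits], claw_arc_length, numeric(1))
  others <- setdiff(digits, reference)
  out <- c(stats::setNames(oo, paste0("Oo_", digits)),
           stats::setNames(al[others] / al[reference],
                           paste0("ALo_", others, "_ratio")))
  attr(out, "reference") <- reference
  out
}
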