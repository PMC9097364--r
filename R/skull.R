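# Jaw mechanical-advantage and functional indices from 2D lateral skull
# geometry.  Inlevers are measured to the articular condyle; outlevers are
# straight-line distances from the condyle.  All indices are dimensionless
# and invariant to rigid motion and uniform scaling of the input
# coordinates.

#' Shoelace area of a simple polygon
#'
#' @param poly Two-column matrix of vertices (closed implicitly).
#' @return Absolute area; orientation-free.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs >= 3 vertices")
  if (polygon_self_intersects(poly)) stop("polygon is self-intersecting")
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# naive O(n^2) segment-intersection test over non-adjacent edges; polygons
# here are small (tens of vertices)
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1L), ])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- cross2(a[1], a[2], b[1], b[2], c[1], c[2])
      d2 <- cross2(a[1], a[2], b[1], b[2], d[1], d[2])
      d3 <- cross2(c[1], c[2], d[1], d[2], a[1], a[2])
      d4 <- cross2(c[1], c[2], d[1], d[2], b[1], b[2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

dist2 <- function(a, b) sqrt(sum((a - b)^2))

# perpendicular distance from point p to the infinite line through a, b
point_line_distance <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) stop("degenerate line: identical defining points")
  abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / len
}

#' Construct a 2D lateral skull geometry
#'
#' Coordinates are Cartesian, y-up, in any consistent unit; only ratios are
#' reported.  The adductor line of action and the depressor attachment are
#' supplied as digitised points, not inferred.
#'
#' @param condyle Articular condyle (quadrate articulation) point.
#' @param bite_anterior,bite_posterior Anterior and posterior bite points.
#' @param adductor_line Two-row matrix: two points on the adductor muscle
#'   line of action.
#' @param depressor Attachment point of the depressor mandibulae.
#' @param occlusal Polyline (matrix) tracing the occlusal margin, rostral to
#'   cranial; recessed teeth should already be excluded.
#' @param outline Outer skull polygon (matrix).
#' @param holes Optional list of hole polygons (orbit, naris, antorbital
#'   fenestra).
#' @param axis Unit vector of the skull long axis (default `c(1, 0)`).
#' @param ao_reverse Logical; reverse the direction of the occlusal
#'   equilibrium-line offset (used for recurved/upturned bills).
#' @return Object of class `skull_geometry`.
#' @export
skull_geometry <- function(condyle, bite_anterior, bite_posterior,
                           adductor_line, depressor, occlusal, outline,
                           holes = list(), axis = c(1, 0),
                           ao_reverse = FALSE) {
  axis <- axis / sqrt(sum(axis^2))
  structure(list(condyle = as.numeric(condyle),
                 bite_anterior = as.numeric(bite_anterior),
                 bite_posterior = as.numeric(bite_posterior),
                 adductor_line = as.matrix(adductor_line),
                 depressor = as.numeric(depressor),
                 occlusal = as.matrix(occlusal),
                 outline = as.matrix(outline),
                 holes = holes, axis = axis, ao_reverse = ao_reverse),
            class = "skull_geometry")
}

# projection extent of the outline onto the long axis = skull length
skull_length <- function(g) {
  proj <- g$outline %*% g$axis
  diff(range(proj))
}

# signed offset of the occlusal equilibrium line: the chord from the rostral
# to the cranial occlusal extreme, translated perpendicular to itself so the
# area ventral to the line balances the empty space dorsal to it.  That
# offset is the length-projected mean signed deviation of the polyline from
# the chord (trapezoidal integration along the chord axis).
ao_offset <- function(g) {
  occ <- g$occlusal
  a <- occ[1L, ]; b <- occ[nrow(occ), ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) stop("degenerate occlusal chord")
  u <- ab / len                       # along-chord unit
  nrm <- c(-u[2L], u[1L])             # normal
  t <- (occ[, 1L] - a[1L]) * u[1L] + (occ[, 2L] - a[2L]) * u[2L]
  d <- (occ[, 1L] - a[1L]) * nrm[1L] + (occ[, 2L] - a[2L]) * nrm[2L]
  # integral of deviation over the chord coordinate / chord length
  dt <- diff(t)
  off <- sum((d[-1L] + d[-length(d)]) / 2 * dt) / (t[length(t)] - t[1L])
  if (isTRUE(g$ao_reverse)) -off else off
}

#' Jaw functional indices from lateral skull geometry
#'
#' Returns the six dimensionless indices:
#' \describe{
#'   \item{AMA}{anterior jaw-closing mechanical advantage: perpendicular
#'     distance from the condyle to the adductor line of action (inlever)
#'     over the condyle-to-anterior-bite-point distance (outlever).}
#'   \item{PMA}{posterior jaw-closing mechanical advantage: same inlever
#'     over the condyle-to-posterior-bite-point distance.}
#'   \item{OMA}{jaw-opening mechanical advantage: condyle-to-depressor
#'     attachment distance over the anterior outlever.}
#'   \item{AO}{relative articular offset: magnitude of the occlusal
#'     equilibrium-line offset over skull length.}
#'   \item{MCH}{maximum cranial height perpendicular to the long axis over
#'     skull length.}
#'   \item{ACH}{average cranial height: outer-outline area (holes not
#'     subtracted by default) divided by skull length, over skull length.}
#' }
#'
#' @param g A [skull_geometry()].
#' @param subtract_holes If `TRUE`, hole areas are subtracted in ACH
#'   (sensitivity variant; the default keeps holes in, the configuration
#'   with the strongest predictive power).
#' @return Named numeric vector AMA, PMA, OMA, AO, MCH, ACH.
#' @export
functional_indices <- function(g, subtract_holes = FALSE) {
  stopifnot(inherits(g, "skull_geometry"))
  inlever <- point_line_distance(g$condyle, g$adductor_line[1L, ],
                                 g$adductor_line[2L, ])
  out_ant <- dist2(g$condyle, g$bite_anterior)
  out_post <- dist2(g$condyle, g$bite_posterior)
  if (out_ant == 0 || out_post == 0) stop("zero outlever")
  L <- skull_length(g)
  area <- polygon_area(g$outline)
  if (subtract_holes && length(g$holes))
    area <- area - sum(vapply(g$holes, polygon_area, numeric(1)))
  nrm <- c(-g$axis[2L], g$axis[1L])
  heights <- g$outline %*% nrm
  c(AMA = inlever / out_ant,
    PMA = inlever / out_post,
    OMA = dist2(g$condyle, g$depressor) / out_ant,
    AO  = abs(ao_offset(g)) / L,
    MCH = diff(range(heights)) / L,
    ACH = (area / L) / L)
}
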