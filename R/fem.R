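# Minimal 2D plane-strain linear-elastic solver with constant-strain
# triangles (CST), reproducing the comparative jaw-model protocol: two
# isotropic materials (bone and rhamphotheca), a single resultant muscle
# force at the attachment node, an articular pin (both translations fixed),
# a dorsoventral constraint at the bite point, and square-root-of-area load
# scaling so geometrically similar models accrue identical strains.
#
# Unit convention: mm, N, MPa; strains are dimensionless and reported
# multiplied by 1e6 (microstrain).

#' Default material set for jaw models
#'
#' Homogeneous isotropic properties matched to in vitro avian strain-gauge
#' work: bone E = 7000 MPa, rhamphotheca E = 3000 MPa, both nu = 0.35.
#' @return Named list of materials, each `list(E, nu)`.
#' @export
jaw_materials <- function() {
  list(bone = list(E = 7000, nu = 0.35),
       rhamphotheca = list(E = 3000, nu = 0.35))
}

#' Reference muscle load magnitude
#'
#' The arbitrary reference magnitude applied to the smallest model; all
#' other models scale from it by [scale_load()] so only relative strains
#' matter.
#' @param config Optional list with entry `base_load_N`.
#' @return Load in N (default 6).
#' @export
base_load <- function(config = NULL) {
  if (!is.null(config$base_load_N)) config$base_load_N else 6
}

#' Plane-strain constitutive matrix
#'
#' D = E/((1+nu)(1-2nu)) * [[1-nu, nu, 0], [nu, 1-nu, 0],
#' [0, 0, (1-2nu)/2]], mapping (eps_xx, eps_yy, gamma_xy) to
#' (sigma_xx, sigma_yy, tau_xy).
#'
#' @param mat List with Young's modulus `E` (MPa) and Poisson ratio `nu`.
#' @return 3x3 symmetric positive-definite matrix (MPa).
#' @export
plane_strain_matrix <- function(mat) {
  E <- mat$E; nu <- mat$nu
  if (E <= 0) stop("E must be positive")
  if (nu < 0 || nu >= 0.5) stop("plane strain requires 0 <= nu < 0.5")
  E / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0,
             nu, 1 - nu, 0,
             0, 0, (1 - 2 * nu) / 2), 3, 3, byrow = TRUE)
}

#' Construct a plane triangle mesh
#'
#' @param nodes Two-column matrix of node coordinates (mm).
#' @param triangles Three-column integer matrix of node indices,
#'   counter-clockwise.
#' @param material Character vector, one material id per triangle.
#' @return Object of class `plane_mesh`.
#' @export
plane_mesh <- function(nodes, triangles, material) {
  nodes <- as.matrix(nodes); triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (length(material) != nrow(triangles))
    stop("one material id per triangle required")
  a <- triangle_areas(nodes, triangles)
  if (any(a <= 0)) stop("non-positive triangle area (check winding order)")
  used <- sort(unique(as.vector(triangles)))
  if (!identical(used, seq_len(nrow(nodes))))
    stop("orphan nodes present")
  structure(list(nodes = nodes, triangles = triangles,
                 material = as.character(material)),
            class = "plane_mesh")
}

triangle_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Total mesh area
#' @param mesh A `plane_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$nodes, mesh$triangles))

#' Construct a load case
#'
#' @param load_node Node index where the muscle force acts.
#' @param force Either a length-2 force vector (N) or `NULL` if
#'   `magnitude`/`angle_deg` are given.
#' @param magnitude,angle_deg Force magnitude (N) and angle measured from
#'   the coronal (long-axis/horizontal) plane in degrees; the force pulls
#'   up-and-back at `angle_deg` above horizontal toward negative x.
#' @param pin_node Node fixed in both translations (articular glenoid).
#' @param bite_node Node fixed dorsoventrally (rostral bite point).
#' @param bite_normal Unit direction of the bite constraint (default
#'   dorsoventral, `c(0, 1)`); rotates with the model under rigid rotation.
#' @return Object of class `load_case`.
#' @export
load_case <- function(load_node, force = NULL, magnitude = NULL,
                      angle_deg = 45, pin_node, bite_node,
                      bite_normal = c(0, 1)) {
  if (is.null(force)) {
    if (is.null(magnitude)) stop("give `force` or `magnitude`")
    a <- angle_deg * pi / 180
    force <- magnitude * c(-cos(a), sin(a))
  }
  ids <- c(load_node, pin_node, bite_node)
  if (anyDuplicated(ids)) stop("load, pin and bite nodes must be distinct")
  structure(list(load_node = as.integer(load_node),
                 force = as.numeric(force),
                 pin_node = as.integer(pin_node),
                 bite_node = as.integer(bite_node),
                 bite_normal = bite_normal / sqrt(sum(bite_normal^2))),
            class = "load_case")
}

# element strain-displacement matrix B (3 x 6) and area for one CST
cst_B <- function(p1, p2, p3) {
  A2 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
  b <- c(p2[2] - p3[2], p3[2] - p1[2], p1[2] - p2[2])
  c_ <- c(p3[1] - p2[1], p1[1] - p3[1], p2[1] - p1[1])
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b
  B[2, c(2, 4, 6)] <- c_
  B[3, c(1, 3, 5)] <- c_
  B[3, c(2, 4, 6)] <- b
  list(B = B / A2, area = A2 / 2)
}

#' Solve a plane-strain finite-element model
#'
#' Assembles the CST global stiffness (unit thickness), applies the point
#' load and the pin/bite constraints by row/column elimination, solves the
#' reduced sparse system, and returns nodal displacements, per-element
#' strain tensors and the total maximum in-plane principal strain
#' eps1 = (exx+eyy)/2 + sqrt(((exx-eyy)/2)^2 + (gxy/2)^2) in microstrain.
#'
#' @param mesh A [plane_mesh()].
#' @param materials Named list of materials as in [jaw_materials()].
#' @param case A [load_case()]; alternatively supply `forces`/`fixed_dofs`
#'   directly for general boundary conditions (validation oracles, patch
#'   and beam tests).
#' @param forces Optional n x 2 matrix of nodal forces (N).
#' @param fixed_dofs Optional integer vector of constrained global dofs
#'   (node i has dofs 2i-1 = x, 2i = y), held at zero.
#' @return Object of class `fe_result`: `displacements` (n x 2, mm),
#'   `strain` (exx, eyy, gxy per element), `principal_micro` (microstrain),
#'   `area` (mm^2 per element), `reactions` (forces at constrained dofs, N).
#' @export
fem_solve <- function(mesh, materials = jaw_materials(), case = NULL,
                      forces = NULL, fixed_dofs = NULL) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$triangles)
  Dm <- lapply(materials, plane_strain_matrix)
  miss <- setdiff(unique(mesh$material), names(Dm))
  if (length(miss)) stop("materials without properties: ",
                         paste(miss, collapse = ", "))
  Bs <- vector("list", ne)
  areas <- numeric(ne)
  trip_i <- vector("list", ne); trip_j <- vector("list", ne)
  trip_x <- vector("list", ne)
  for (e in seq_len(ne)) {
    tri <- mesh$triangles[e, ]
    bb <- cst_B(mesh$nodes[tri[1L], ], mesh$nodes[tri[2L], ],
                mesh$nodes[tri[3L], ])
    Bs[[e]] <- bb$B
    areas[e] <- bb$area
    Ke <- bb$area * crossprod(bb$B, Dm[[mesh$material[e]]] %*% bb$B)
    dofs <- as.vector(rbind(2L * tri - 1L, 2L * tri))
    trip_i[[e]] <- rep(dofs, each = 6L)
    trip_j[[e]] <- rep(dofs, times = 6L)
    trip_x[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(2L * nn, 2L * nn))
  f <- numeric(2L * nn)
  Tb <- NULL
  if (!is.null(case)) {
    f[2L * case$load_node - 1L] <- case$force[1L]
    f[2L * case$load_node] <- case$force[2L]
    # the bite constraint acts along bite_normal; rotate that node's dof
    # pair into the (normal, tangent) frame and eliminate the normal dof
    nrm <- if (is.null(case$bite_normal)) c(0, 1) else case$bite_normal
    Tb <- cbind(nrm, c(-nrm[2L], nrm[1L]))
    bd <- c(2L * case$bite_node - 1L, 2L * case$bite_node)
    K[, bd] <- K[, bd] %*% Tb
    K[bd, ] <- t(Tb) %*% K[bd, ]
    f[bd] <- t(Tb) %*% f[bd]
    fixed <- c(2L * case$pin_node - 1L, 2L * case$pin_node,
               2L * case$bite_node - 1L)
  } else {
    if (is.null(fixed_dofs)) stop("no constraints supplied")
    fixed <- as.integer(fixed_dofs)
  }
  if (!is.null(forces)) {
    f[seq(1L, 2L * nn, by = 2L)] <- f[seq(1L, 2L * nn, by = 2L)] + forces[, 1L]
    f[seq(2L, 2L * nn, by = 2L)] <- f[seq(2L, 2L * nn, by = 2L)] + forces[, 2L]
  }
  free <- setdiff(seq_len(2L * nn), fixed)
  u <- numeric(2L * nn)
  sol <- tryCatch(
    Matrix::solve(K[free, free], f[free]),
    error = function(e) stop("singular system: insufficient constraints (",
                             conditionMessage(e), ")"))
  u[free] <- as.numeric(sol)
  reactions <- as.numeric(K[fixed, ] %*% u) - f[fixed]
  if (!is.null(Tb)) {
    bd <- c(2L * case$bite_node - 1L, 2L * case$bite_node)
    u[bd] <- Tb %*% u[bd]          # back to global frame
  }
  strain <- matrix(0, ne, 3, dimnames = list(NULL, c("exx", "eyy", "gxy")))
  for (e in seq_len(ne)) {
    tri <- mesh$triangles[e, ]
    dofs <- as.vector(rbind(2L * tri - 1L, 2L * tri))
    strain[e, ] <- Bs[[e]] %*% u[dofs]
  }
  centre <- (strain[, 1L] + strain[, 2L]) / 2
  radius <- sqrt(((strain[, 1L] - strain[, 2L]) / 2)^2 + (strain[, 3L] / 2)^2)
  structure(list(displacements = matrix(u, nn, 2, byrow = TRUE),
                 strain = strain,
                 principal_micro = (centre + radius) * 1e6,
                 area = areas,
                 reactions = if (!is.null(case))
                   stats::setNames(reactions, c("pin_x", "pin_y", "bite_n"))
                 else stats::setNames(reactions, fixed)),
            class = "fe_result")
}

#' Structured rectangular mesh
#'
#' Regular grid of quadrilaterals split into counter-clockwise triangle
#' pairs; the workhorse for patch, beam and convergence oracles.
#'
#' @param length,height Rectangle dimensions (mm).
#' @param nx,ny Elements along x and y.
#' @param material Material id for all elements.
#' @param x0,y0 Lower-left corner.
#' @return A `plane_mesh`; attribute `grid` holds `nx`, `ny` and a
#'   `node_id(i, j)` lookup (1-based grid indices).
#' @export
rect_mesh <- function(length, height, nx, ny, material = "bone",
                      x0 = 0, y0 = 0) {
  xs <- seq(x0, x0 + length, length.out = nx + 1L)
  ys <- seq(y0, y0 + height, length.out = ny + 1L)
  node_id <- function(i, j) (i - 1L) * (ny + 1L) + j
  nodes <- do.call(rbind, lapply(seq_len(nx + 1L),
                                 function(i) cbind(xs[i], ys)))
  tris <- matrix(0L, 2L * nx * ny, 3L)
  k <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    a <- node_id(i, j); b <- node_id(i + 1L, j)
    c_ <- node_id(i + 1L, j + 1L); d <- node_id(i, j + 1L)
    tris[k + 1L, ] <- c(a, b, c_)
    tris[k + 2L, ] <- c(a, c_, d)
    k <- k + 2L
  }
  m <- plane_mesh(nodes, tris, rep(material, nrow(tris)))
  attr(m, "grid") <- list(nx = nx, ny = ny, node_id = node_id)
  m
}

#' Scale a reference load for a model of different size
#'
#' In a unit-thickness plane model, stress scales as force/length and model
#' area as length^2, so holding the stress (and strain) state constant
#' across geometrically similar models requires F proportional to sqrt(A):
#' F = F_ref * (A_target/A_ref)^exponent with exponent 0.5.
#'
#' @param F_ref Reference force (N).
#' @param area_ref,area_target Model areas (mm^2).
#' @param exponent Scaling exponent (default 0.5; exposed for sensitivity).
#' @return Scaled force magnitude (N).
#' @export
scale_load <- function(F_ref, area_ref, area_target, exponent = 0.5) {
  if (area_ref <= 0 || area_target <= 0) stop("areas must be positive")
  F_ref * (area_target / area_ref)^exponent
}

#' Extract the strain field from an FE result
#'
#' Uses the magnitude convention: the per-element total maximum in-plane
#' principal strain is reported as an absolute value, so interval ranges
#' can start at zero.
#'
#' @param result An `fe_result`.
#' @param label Model label carried through the intervals pipeline.
#' @return Object of class `strain_field`: `strain` (microstrain, >= 0),
#'   `area` (mm^2), `label`.
#' @export
strain_field <- function(result, label = "model") {
  structure(list(strain = abs(result$principal_micro), area = result$area,
                 label = label),
            class = "strain_field")
}
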