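# Jaw model construction: mesh an x-monotone lateral jaw outline into CSTs,
# label a dorsal rhamphotheca band, and set up the muscle/pin/bite load
# case.  Lateral jaw profiles are height fields over the long (x) axis, so
# the mesher is a structured "strip" mesher: the region between the bottom
# and top chains of the outline is covered by a regular grid of
# quadrilaterals split into triangles.  Outlines that are not x-monotone
# are rejected.

# split an x-monotone simple polygon into bottom and top chains, each a
# function of x over [xmin, xmax]
outline_chains <- function(outline) {
  outline <- as.matrix(outline)
  n <- nrow(outline)
  i_min <- which.min(outline[, 1L]); i_max <- which.max(outline[, 1L])
  idx <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1L:to)
  }
  chain1 <- outline[idx(i_min, i_max), , drop = FALSE]
  chain2 <- outline[rev(idx(i_max, i_min)), , drop = FALSE]
  for (ch in list(chain1, chain2))
    if (any(diff(ch[, 1L]) < 0))
      stop("outline is not x-monotone; strip meshing requires a profile ",
           "that is single-valued above and below along the long axis")
  if (mean(chain1[, 2L]) > mean(chain2[, 2L])) {
    tmp <- chain1; chain1 <- chain2; chain2 <- tmp
  }
  # vertical end edges duplicate x at the chain ends; keep the extreme y
  # appropriate for each chain so the strip keeps its full local thickness
  dedupe <- function(ch, keep) {
    ys <- tapply(ch[, 2L], ch[, 1L], keep)
    x <- as.numeric(names(ys))
    o <- order(x)
    cbind(x[o], as.numeric(ys)[o])
  }
  list(bottom = dedupe(chain1, min), top = dedupe(chain2, max))
}

chain_y <- function(chain, x) {
  stats::approx(chain[, 1L], chain[, 2L], xout = x, rule = 2)$y
}

#' Build a two-material jaw finite-element model from a lateral outline
#'
#' Meshes the outline with a structured grid of constant-strain triangles,
#' labels each element `rhamphotheca` if its centroid lies in the dorsal
#' band occupying `rham_fraction` of the local dorsoventral thickness
#' (default 20% rhamphotheca over 80% bone), and assembles the load case:
#' the muscle resultant at the attachment node (default 45 degrees from the
#' coronal plane), the articular pin, and the dorsoventral bite constraint.
#'
#' @param outline Two-column matrix: simple, x-monotone jaw profile (mm).
#' @param rham_fraction Fraction (0-1) of local thickness that is
#'   rhamphotheca, measured from the dorsal margin.
#' @param attach_point,bite_point,pin_point Length-2 coordinates; snapped to
#'   the nearest mesh node (must lie within `target_h` of one).
#' @param attach_angle_deg Muscle angle from the coronal plane.
#' @param target_h Target element size (mm).
#' @param magnitude Muscle force magnitude (N); default [base_load()].
#' @return List with `mesh` (a [plane_mesh()]) and `case` (a
#'   [load_case()]).
#' @export
build_jaw_model <- function(outline, rham_fraction = 0.2, attach_point,
                            attach_angle_deg = 45, bite_point, pin_point,
                            target_h, magnitude = base_load()) {
  if (rham_fraction < 0 || rham_fraction > 1)
    stop("rham_fraction must lie in [0, 1]")
  ch <- outline_chains(outline)
  xr <- range(outline[, 1L])
  nx <- max(2L, ceiling(diff(xr) / target_h))
  xs <- seq(xr[1L], xr[2L], length.out = nx + 1L)
  ylo <- chain_y(ch$bottom, xs)
  yhi <- chain_y(ch$top, xs)
  if (any(yhi - ylo <= 0))
    stop("outline has zero dorsoventral thickness inside the meshed span")
  ny <- max(2L, ceiling(max(yhi - ylo) / target_h))
  # nodes: column-major grid, (nx+1) columns x (ny+1) rows
  node_id <- function(i, j) (i - 1L) * (ny + 1L) + j
  nodes <- matrix(0, (nx + 1L) * (ny + 1L), 2L)
  for (i in seq_len(nx + 1L)) {
    ys <- seq(ylo[i], yhi[i], length.out = ny + 1L)
    nodes[node_id(i, seq_len(ny + 1L)), ] <- cbind(xs[i], ys)
  }
  tris <- matrix(0L, 2L * nx * ny, 3L)
  k <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    a <- node_id(i, j); b <- node_id(i + 1L, j)
    c_ <- node_id(i + 1L, j + 1L); d <- node_id(i, j + 1L)
    tris[k + 1L, ] <- c(a, b, c_)      # ccw
    tris[k + 2L, ] <- c(a, c_, d)
    k <- k + 2L
  }
  # material by centroid's fractional height in the local thickness
  cx <- (nodes[tris[, 1L], 1L] + nodes[tris[, 2L], 1L] + nodes[tris[, 3L], 1L]) / 3
  cy <- (nodes[tris[, 1L], 2L] + nodes[tris[, 2L], 2L] + nodes[tris[, 3L], 2L]) / 3
  lo_c <- chain_y(ch$bottom, cx); hi_c <- chain_y(ch$top, cx)
  frac <- (cy - lo_c) / (hi_c - lo_c)
  material <- ifelse(frac > 1 - rham_fraction, "rhamphotheca", "bone")
  mesh <- plane_mesh(nodes, tris, material)
  snap <- function(p, what) {
    d2 <- (nodes[, 1L] - p[1L])^2 + (nodes[, 2L] - p[2L])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) > 2 * target_h)
      stop(what, " point lies farther than 2*target_h from any mesh node")
    i
  }
  case <- load_case(load_node = snap(attach_point, "attachment"),
                    magnitude = magnitude, angle_deg = attach_angle_deg,
                    pin_node = snap(pin_point, "pin"),
                    bite_node = snap(bite_point, "bite"))
  list(mesh = mesh, case = case)
}

#' Write a plane mesh to the package's ASCII format
#'
#' Two whitespace-separated tables introduced by `$nodes` / `$elements`
#' headers: node rows `id x y`, element rows `id n1 n2 n3 material`.
#'
#' @param mesh A `plane_mesh`.
#' @param file Output path.
#' @export
write_mesh_ascii <- function(mesh, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines("$nodes", con)
  writeLines(sprintf("%d %.10g %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines("$elements", con)
  writeLines(sprintf("%d %d %d %d %s", seq_len(nrow(mesh$triangles)),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L], mesh$material), con)
  invisible(file)
}

#' Read a plane mesh from the package's ASCII format
#' @param file Path written by [write_mesh_ascii()].
#' @return A `plane_mesh`.
#' @export
read_mesh_ascii <- function(file) {
  lines <- readLines(file)
  i_n <- which(lines == "$nodes"); i_e <- which(lines == "$elements")
  if (length(i_n) != 1L || length(i_e) != 1L) stop("malformed mesh file")
  nd <- read.table(text = lines[(i_n + 1L):(i_e - 1L)])
  el <- read.table(text = lines[(i_e + 1L):length(lines)],
                   colClasses = c("integer", "integer", "integer", "integer",
                                  "character"))
  nodes <- as.matrix(nd[order(nd[[1L]]), 2:3])
  el <- el[order(el[[1L]]), ]
  plane_mesh(nodes, as.matrix(el[, 2:4]), el[[5L]])
}

#' Import triangles from a Gmsh ASCII v2 file
#'
#' Reads `$Nodes` and the 3-node triangle elements (type 2) of a Gmsh
#' MeshFormat 2.x file; the physical tag (first tag) is used as material id.
#'
#' @param file Path to a `.msh` file.
#' @param material_map Optional named vector mapping physical tags to
#'   material names; untagged/unmapped triangles become `"bone"`.
#' @return A `plane_mesh`.
#' @export
read_gmsh2 <- function(file, material_map = NULL) {
  lines <- readLines(file)
  sect <- function(name) {
    s <- which(lines == paste0("$", name)); e <- which(lines == paste0("$End", name))
    if (length(s) != 1L || length(e) != 1L) stop("missing $", name, " section")
    lines[(s + 2L):(e - 1L)]       # skip the count line
  }
  nd <- read.table(text = sect("Nodes"))
  nodes <- as.matrix(nd[order(nd[[1L]]), 2:3])
  el <- strsplit(sect("Elements"), "\\s+")
  tris <- list(); mats <- character(0)
  for (row in el) {
    v <- as.integer(row)
    if (v[2L] != 2L) next                      # only 3-node triangles
    ntags <- v[3L]
    conn <- v[(4L + ntags):(6L + ntags)]
    tris[[length(tris) + 1L]] <- conn
    tag <- if (ntags >= 1L) as.character(v[4L]) else ""
    mats <- c(mats, if (!is.null(material_map) && tag %in% names(material_map))
      material_map[[tag]] else "bone")
  }
  if (!length(tris)) stop("no triangles in Gmsh file")
  plane_mesh(nodes, do.call(rbind, tris), mats)
}

#' Export per-element FE results as CSV
#'
#' Columns: element id, area (mm^2), exx, eyy, gxy, and the total maximum
#' in-plane principal strain in microstrain.
#'
#' @param result An `fe_result`.
#' @param file Output path.
#' @export
write_fe_csv <- function(result, file) {
  df <- data.frame(element = seq_along(result$area), area = result$area,
                   exx = result$strain[, "exx"], eyy = result$strain[, "eyy"],
                   gxy = result$strain[, "gxy"],
                   e1_max_in_plane_micro = result$principal_micro)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
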