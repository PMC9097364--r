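# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check.

# brute-force phylogenetic covariance: shared path length root->MRCA by
# walking parent chains
brute_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
    elen[tree$edge[k, 2]] <- tree$edge.length[k]
  }
  root <- n + 1L
  path_to_root <- function(i) {
    out <- integer(0)
    while (i != root) { out <- c(out, i); i <- parent[i] }
    out
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(elen[shared])
  }
  C
}

# random simple star-shaped polygon around the origin
random_star_polygon <- function(nv, seed) {
  set.seed(seed)
  th <- sort(stats::runif(nv, 0, 2 * pi))
  r <- stats::runif(nv, 0.5, 2)
  cbind(r * cos(th), r * sin(th))
}

# Monte-Carlo area of a star-shaped polygon (point-in-polygon by even-odd)
mc_polygon_area <- function(poly, n = 2e5, seed = 1) {
  set.seed(seed)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- stats::runif(n, xr[1], xr[2]); py <- stats::runif(n, yr[1], yr[2])
  nv <- nrow(poly)
  inside <- logical(n)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# structured cantilever solve used by the beam oracle test
solve_cantilever <- function(nx, ny, L = 20, h = 1, P = -0.1) {
  mesh <- rect_mesh(L, h, nx, ny, y0 = -h / 2)
  nid <- attr(mesh, "grid")$node_id
  forces <- matrix(0, nrow(mesh$nodes), 2)
  tipcol <- nid(nx + 1, 1:(ny + 1))
  forces[tipcol, 2] <- P / (ny + 1)
  left <- nid(1, 1:(ny + 1))
  res <- fem_solve(mesh, case = NULL, forces = forces,
                   fixed_dofs = c(2 * left - 1, 2 * left))
  mean(res$displacements[tipcol, 2])
}

# one planted-fossil end-to-end run (synthetic cohort -> classifier + mass
# proxies -> consensus); returns logical flags
planted_fossil_run <- function(s) {
  set.seed(s)
  tr <- simulate_tree(32, seed = s)
  guilds <- c("InvertivoreH", "Piscivore", "GranivoreS", "Generalist")
  grp <- stats::setNames(rep(guilds, 8), tr$tip.label)
  eff <- guild_trait_effects(guilds, n_traits = 3)
  te <- synth_calibration()$trait_effects
  Y <- simulate_bm_traits(tr, sigma2 = te$sigma2, group_map = grp,
                          effects = eff, noise_sd = te$noise_sd,
                          seed = s + 1)
  sdm <- sqrt(te$sigma2 * 94 + te$noise_sd^2)
  fossil <- matrix(eff["InvertivoreH", ] + stats::rnorm(3, 0, sdm), 1,
                   dimnames = list("fossil1", NULL))
  cls <- run_classifier_proxy(Y, grp[rownames(Y)], fossil, method = "lda",
                              proxy = "fea")
  repeat { mg <- synth_masses("InvertivoreH", 1); if (mg < 300) break }
  est <- structure(list(mean = mg, lower = mg / 1.25, upper = mg * 1.25),
                   class = "mass_estimate")
  cons <- synthesize(list(cls, run_mass_proxy(list(fossil1 = est))))
  c(in_shortlist = "InvertivoreH" %in% cons$shortlist$fossil1,
    head_invertivore = cons$shortlist$fossil1[1] %in%
      c("InvertivoreH", "InvertivoreM", "InvertivoreS"))
}

# jaw MWAM for one synthetic draw with sqrt-area-scaled load
jaw_mwam <- function(diet, seed, target_h = 1.2, area_ref = 60) {
  j <- synth_jaw(diet, seed = seed)
  mod <- build_jaw_model(j$outline, attach_point = j$attach_point,
                         bite_point = j$bite_point, pin_point = j$pin_point,
                         target_h = target_h)
  mag <- scale_load(base_load(), area_ref, mesh_area(mod$mesh))
  mod$case$force <- mod$case$force / sqrt(sum(mod$case$force^2)) * mag
  mwam(strain_field(fem_solve(mod$mesh, case = mod$case)))
}
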