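# Synthetic-data generators.  These stand in for museum measurements and
# specimen photographs: they reproduce the statistical structure the
# analysis assumes (Brownian traits on a time tree with additive guild
# effects, three-point claw arcs with guild-dependent curvature, x-monotone
# jaw profiles whose depth tracks jaw strength, diet percentage rows that
# classify back to their generating category) without attempting anatomical
# realism.  Every generator is a deterministic function of (config, seed).

#' Guild calibration constants for the generators
#'
#' One place for every generator's guild-level parameters so synthetic
#' "worlds" are auditable.  Mass means follow the reported guild summary
#' statistics (invertivores 75 g, vertivores 1426 g, folivores+frugivores
#' 732 g, granivores+nectarivores 41 g) with a common log10 sd of 0.45
#' back-derived from the printed ranges; claw curvature centres ground
#' birds near 40 degrees and raptors near 100; jaw aspect (depth/length)
#' separates strong-jawed (deep) from weak-jawed (slender) guilds.
#'
#' @return Nested list of calibration constants.
#' @export
synth_calibration <- function() {
  list(
    mass_log10 = list(
      sd = 0.45,
      mean = c(InvertivoreH = log10(75), InvertivoreM = log10(75),
               InvertivoreS = log10(75),
               Piscivore = log10(1426), Scavenger = log10(1426),
               TetrapodHunter = log10(1426),
               Folivore = log10(1537), FrugivoreH = log10(259),
               FrugivoreS = log10(259),
               GranivoreH = log10(45), GranivoreS = log10(45),
               Nectarivore = log10(36), Generalist = log10(200))),
    claw_oo = list(
      sd = 8,
      mean = c(Ground = 40, Perch = 75, Restraint = 100, Strike = 95,
               Suffocate = 105, Pierce = 110, Scavenger = 65)),
    jaw_aspect = list(
      sd = 0.02,
      # depth/length; deep = strong jaw (low strain), slender = weak
      mean = c(Folivore = 0.24, FrugivoreH = 0.28, FrugivoreS = 0.22,
               GranivoreH = 0.30, GranivoreS = 0.22, Nectarivore = 0.24,
               Generalist = 0.13, InvertivoreH = 0.11, InvertivoreM = 0.11,
               InvertivoreS = 0.20, Piscivore = 0.11, Scavenger = 0.13,
               TetrapodHunter = 0.13)),
    trait_effects = list(
      # separation between guild trait centroids, in units of the marginal
      # within-guild sd; 4 sd gives clearly recoverable planted structure
      # (reclassification kappa ~ 0.95), the regime the planted-structure
      # tests are meant to exercise
      separation_sd = 4,
      noise_sd = 0.3,
      sigma2 = 0.01),
    tree = list(birth = 0.1, depth_ma = 94))
}

#' Default guild trait-effect vectors
#'
#' Places up to `n_traits + 1` guild centroids at the vertices of a regular
#' simplex so every pair of guilds is separated by the same distance:
#' `separation` times the marginal within-guild trait sd (Brownian variance
#' at the tree depth plus measurement noise, from [synth_calibration()]).
#'
#' @param guilds Character vector of guild labels (at most `n_traits + 1`).
#' @param n_traits Trait dimension.
#' @param separation Centroid separation in within-guild sds; default from
#'   [synth_calibration()].
#' @return Matrix (guilds x traits) of additive effects.
#' @export
guild_trait_effects <- function(guilds, n_traits = 3, separation = NULL) {
  cal <- synth_calibration()
  te <- cal$trait_effects
  if (is.null(separation)) separation <- te$separation_sd
  k <- length(guilds)
  if (k > n_traits + 1)
    stop("at most n_traits + 1 guilds fit a regular simplex")
  # regular simplex with unit edge in n_traits dimensions
  V <- diag(1, k, n_traits)
  ctr <- colMeans(V)
  V <- sweep(V, 2L, ctr)
  edge <- sqrt(sum((V[1, ] - V[2, ])^2))
  sd_marginal <- sqrt(te$sigma2 * cal$tree$depth_ma + te$noise_sd^2)
  V <- V / edge * separation * sd_marginal
  rownames(V) <- guilds
  V
}

#' Pedal-ecology categories used by the claw generator
#' @return Character vector.
#' @export
pedal_categories <- function() {
  c("Ground", "Perch", "Restraint", "Strike", "Suffocate", "Pierce",
    "Scavenger")
}

#' Simulate a pure-birth time tree rescaled to a fixed depth
#'
#' Yule trees conditioned on the number of tips, rescaled linearly so the
#' root-to-tip depth is `depth_ma` (94 Ma by default, the avian-portion
#' depth used throughout).
#'
#' @param n_taxa Number of tips (>= 2).
#' @param depth_ma Target depth (Ma).
#' @param seed Integer seed.
#' @return A `phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, depth_ma = 94, seed = NULL) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = synth_calibration()$tree$birth, death = 0)
  scale_tree_depth(tr, depth_ma)
}

#' Simulate Brownian traits with additive group effects
#'
#' Each trait column is multivariate normal with covariance sigma2 * C
#' (C the Brownian covariance of the tree), plus the group effect of each
#' tip's diet/ecology label, plus iid measurement noise.
#'
#' @param tree A `phylo`.
#' @param sigma2 Brownian rate per Ma (trait variance units).
#' @param group_map Named character vector tip -> group label (optional).
#' @param effects Matrix of group effect vectors (groups x traits), rownames
#'   = group labels; or `NULL` for no effects.
#' @param noise_sd Standard deviation of iid measurement noise.
#' @param n_traits Number of trait columns (ignored if `effects` given).
#' @param seed Integer seed.
#' @return Numeric matrix, rows = tips (rownames = tip labels).
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, group_map = NULL,
                               effects = NULL, noise_sd = 0, n_traits = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  p <- if (!is.null(effects)) ncol(effects) else n_traits
  e <- eigen(C, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  Y <- L %*% matrix(stats::rnorm(n * p, sd = sqrt(sigma2)), n, p)
  rownames(Y) <- rownames(C)
  if (!is.null(effects)) {
    if (is.null(group_map)) stop("effects given without a group_map")
    Y <- Y + effects[group_map[rownames(Y)], , drop = FALSE]
  }
  if (noise_sd > 0) Y <- Y + stats::rnorm(n * p, sd = noise_sd)
  colnames(Y) <- paste0("trait", seq_len(p))
  Y
}

# exact three-point arc with central angle theta (radians), arc length s,
# random rigid placement
arc_landmarks <- function(digit, theta_deg, arc_len, rot, shift) {
  theta <- theta_deg * pi / 180
  r <- arc_len / theta
  pts <- vapply(c(0, theta / 2, theta),
                function(a) c(r * cos(a), r * sin(a)), numeric(2))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  pts <- R %*% pts + shift
  claw_landmarks(digit, pts[, 1L], pts[, 2L], pts[, 3L])
}

#' Generate four claw landmark sets for a pedal-ecology label
#'
#' Draws per-digit curvature around the guild's configured mean (ground
#' birds straight, raptors strongly curved) and arc lengths around a fixed
#' digit-size profile, and emits exact three-point arcs under a random
#' rigid placement, so the recovered curvature equals the generating angle.
#'
#' @param profile A label from [pedal_categories()].
#' @param seed Integer seed.
#' @return Named list of four [claw_landmarks()] (`DI`..`DIV`) with
#'   attribute `generating` (the drawn angles and arc lengths).
#' @export
synth_claws <- function(profile, seed = NULL) {
  cal <- synth_calibration()$claw_oo
  if (!profile %in% pedal_categories()) stop("unknown pedal label: ", profile)
  if (!is.null(seed)) set.seed(seed)
  digits <- c("DI", "DII", "DIII", "DIV")
  # relative digit sizes: DIII longest, DI shortest
  size <- c(DI = 0.7, DII = 0.9, DIII = 1.0, DIV = 0.85)
  oo <- pmin(pmax(stats::rnorm(4, cal$mean[[profile]], cal$sd), 10), 350)
  alo <- size * 10 * exp(stats::rnorm(4, 0, 0.05))
  claws <- lapply(seq_along(digits), function(i)
    arc_landmarks(digits[i], oo[i], alo[i],
                  rot = stats::runif(1, 0, 2 * pi),
                  shift = stats::runif(2, -5, 5)))
  names(claws) <- digits
  attr(claws, "generating") <- list(oo = stats::setNames(oo, digits),
                                    alo = stats::setNames(alo, digits))
  claws
}

#' Generate a jaw outline and model points for a diet label
#'
#' Produces a slender (weak-jawed guilds) or deep (strong-jawed guilds)
#' x-monotone lateral profile with the bite point at the rostral tip, the
#' articular pin at the caudoventral corner, and the muscle attachment on
#' the dorsal margin at three-quarters of the jaw length.
#'
#' @param diet A label from [diet_categories()].
#' @param length_mm Jaw length (mm).
#' @param seed Integer seed.
#' @return List: `outline` (polygon matrix), `attach_point`, `bite_point`,
#'   `pin_point`, `aspect` (drawn depth/length).
#' @export
synth_jaw <- function(diet, length_mm = 30, seed = NULL) {
  cal <- synth_calibration()$jaw_aspect
  if (!diet %in% diet_categories()) stop("unknown diet label: ", diet)
  if (!is.null(seed)) set.seed(seed)
  aspect <- max(0.05, stats::rnorm(1, cal$mean[[diet]], cal$sd))
  L <- length_mm
  d_max <- aspect * L
  d_tip <- 0.25 * d_max
  xs <- seq(0, L, length.out = 13)
  # dorsal margin rises from the tip toward the jaw joint
  top <- d_tip + (d_max - d_tip) * (xs / L)^0.8
  outline <- rbind(cbind(xs, 0), cbind(rev(xs), rev(top)))
  list(outline = outline,
       attach_point = c(0.75 * L, d_tip + (d_max - d_tip) * 0.75^0.8),
       bite_point = c(0, 0),
       pin_point = c(L, 0),
       aspect = aspect)
}

#' Generate a diet percentage row that classifies back to its label
#'
#' Constructive inverse of [classify_diet()]: for each requested label the
#' row meets that label's cut-off at the requested specialist level (with
#' the appropriate hardness/mode annotation), and Generalist rows keep
#' every category at or below the Generalist maximum.
#'
#' @param labels Character vector of diet categories.
#' @param level `"standard"` or `"semi"`.
#' @param seed Integer seed.
#' @return List of [diet_profile()]s, one per label, named by label.
#' @export
synth_diet_table <- function(labels, level = c("standard", "semi"),
                             seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  co <- diet_cutoffs()
  one <- function(label) {
    base <- sub("^(Invertivore|Frugivore|Granivore)[HMS]$", "\\1", label)
    ann <- list()
    if (grepl("^Invertivore", label))
      ann$invert_hardness <- c(H = "hard", M = "medium",
                               S = "soft")[[substring(label, 12L)]]
    if (grepl("^Frugivore", label))
      ann$fruit_hardness <- c(H = "hard", S = "soft")[[substring(label, 10L)]]
    if (grepl("^Granivore", label))
      ann$granivory_mode <- c(H = "husk", S = "swallow")[[substring(label, 10L)]]
    if (base == "Generalist") {
      gmax <- co[co$diet == "Generalist",
                 if (level == "standard") "standard" else "semi"]
      # spread across four categories, none above the Generalist maximum
      pct <- c(Inv = min(30, gmax), Fruit = 25, Seed = 25)
      pct <- c(pct, PlantO = 100 - sum(pct))
      return(do.call(diet_profile, c(as.list(pct), ann)))
    }
    row <- co[co$diet == base, ]
    need <- row[[if (level == "standard") "standard" else "semi"]]
    main <- min(100, need + stats::runif(1, 0, max(0, (100 - need) / 2)))
    col <- row$column
    rest <- 100 - main
    # remainder goes to a neutral filler category distinct from the tested one
    filler <- if (col == "PlantO") "Fruit" else "PlantO"
    args <- stats::setNames(list(main, rest), c(col, filler))
    if (col == "Tetr") {            # Tetr is post-merge: emit as Ect + End
      args <- stats::setNames(list(main / 2, main / 2, rest),
                              c("Ect", "End", "PlantO"))
    }
    do.call(diet_profile, c(args, ann))
  }
  out <- lapply(labels, one)
  names(out) <- labels
  out
}

#' Draw body masses for a diet category
#'
#' Lognormal masses with the guild's calibrated log10 mean and the common
#' log10 sd.
#'
#' @param diet Diet category label.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric masses (g).
#' @export
synth_masses <- function(diet, n, seed = NULL) {
  cal <- synth_calibration()$mass_log10
  if (!diet %in% names(cal$mean)) stop("unknown diet label: ", diet)
  if (!is.null(seed)) set.seed(seed)
  10^stats::rnorm(n, cal$mean[[diet]], cal$sd)
}
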