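#' Read a time-scaled phylogeny from a Newick string or file
#'
#' Trees are represented as [ape::phylo] objects with branch lengths in
#' million years (Ma).  Duplicate tip labels and missing branch lengths are
#' rejected because every downstream computation (Brownian covariance,
#' grafting, signal statistics) assumes a uniquely labelled, fully
#' length-annotated tree.
#'
#' @param text Newick string (terminated by `;`).
#' @param file Path to a Newick file; exactly one of `text`/`file` given.
#' @return An object of class `phylo` with `edge.length` set.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tr <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    ape::read.tree(file = file)
  }
  if (is.null(tr)) {
    # locate first structural problem crudely for the error message
    pos <- regexpr("[^(),:;A-Za-z0-9_.' \t-]", if (is.null(text)) "" else text)
    stop("Newick parse error",
         if (pos > 0) sprintf(" near character %d", pos) else "")
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; time-scaled trees are required")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Write a phylogeny to a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

# Root-to-node depth (Ma from the root, increasing toward the present) for
# every node, in ape node numbering.
node_depths <- function(tree) {
  n  <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  dep <- numeric(nn)
  root <- n + 1L
  # edges in preorder (parents before children)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; c <- ord$edge[k, 2L]
    dep[c] <- dep[p] + ord$edge.length[k]
  }
  dep[root] <- 0
  dep
}

#' Maximum root-to-tip depth of a tree
#' @param tree A `phylo` object.
#' @return Depth in Ma.
#' @export
tree_depth <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Linearly rescale a tree to a target root-to-tip depth
#'
#' Every branch length is multiplied by one constant so that the maximum
#' root-to-tip depth equals `target_depth` (e.g. 94 Ma for the avian portion
#' of a composite tree, or 131 Ma for an Ornithothoraces-rooted tree).
#' Branch-length ratios are preserved exactly.
#'
#' @param tree A `phylo` object with positive depth.
#' @param target_depth Target depth in Ma.
#' @return Rescaled `phylo`.
#' @export
scale_tree_depth <- function(tree, target_depth) {
  d <- tree_depth(tree)
  if (d <= 0) stop("tree has zero depth; cannot rescale")
  tree$edge.length <- tree$edge.length * (target_depth / d)
  tree
}

#' Graft a fossil clade onto a host tree at a stated stem age
#'
#' Builds a non-ultrametric time tree in which fossil tips terminate at the
#' age of their oldest occurrence.  The grafted clade is described by its
#' topology only; internal divergence ages are reconstructed as the oldest
#' descendant tip age plus `spacing` (default 0.01 Ma, i.e. a 10,000-year
#' divergence), applied recursively so nested splits stack.  The stem
#' attaches to the edge subtending `attach_at` in the host at `stem_age`
#' before present.
#'
#' @param host Host `phylo`; treated as ultrametric with tips at the present
#'   (age 0).  Depths are ages before present: a host of depth D has its root
#'   at D Ma.
#' @param attach_at Tip label or internal node number of the host; the graft
#'   is inserted on the edge leading to this node.  For attachment at the
#'   host root's own stem use `attach_at = "root"`, which creates a new root
#'   at `stem_age`.
#' @param subtree A `phylo` giving topology of the grafted clade (branch
#'   lengths ignored), or a single tip label (character scalar) for a
#'   one-tip graft.
#' @param stem_age Age (Ma before present) of the divergence between the
#'   graft and the host lineage.
#' @param tip_ages Named numeric vector, ages (Ma) of each grafted tip.
#' @param spacing Divergence spacing in Ma for unstated internal ages.
#' @return A `phylo` containing host and graft tips.
#' @export
graft_clade <- function(host, attach_at, subtree, stem_age, tip_ages,
                        spacing = 0.01) {
  graft <- build_fossil_clade(subtree, tip_ages, spacing)
  root_age <- attr(graft, "root_age")   # age of the graft's basal divergence
  if (stem_age <= root_age)
    stop(sprintf("stem age %.4f not older than graft root age %.4f",
                 stem_age, root_age))
  graft$root.edge <- stem_age - root_age
  host_depth <- tree_depth(host)
  if (identical(attach_at, "root")) {
    if (stem_age <= host_depth)
      stop("stem_age must exceed host depth to attach at the root stem")
    host$root.edge <- stem_age - host_depth
    out <- ape::bind.tree(host, graft, where = ape::Ntip(host) + 1L,
                          position = stem_age - host_depth)
  } else {
    node <- if (is.character(attach_at)) {
      m <- match(attach_at, host$tip.label)
      if (is.na(m)) stop("attach point not found: ", attach_at)
      m
    } else as.integer(attach_at)
    dep <- node_depths(host)
    node_age <- host_depth - dep[node]
    parent <- host$edge[host$edge[, 2L] == node, 1L]
    if (length(parent) == 0L) stop("cannot attach on the root node itself; use \"root\"")
    parent_age <- host_depth - dep[parent]
    if (stem_age <= node_age || stem_age >= parent_age)
      stop(sprintf(
        "stem age %.4f outside the age span (%.4f, %.4f) of the attachment edge",
        stem_age, node_age, parent_age))
    out <- ape::bind.tree(host, graft, where = node,
                          position = stem_age - node_age)
  }
  out <- ape::collapse.singles(out)
  if (any(out$edge.length < 0)) stop("grafting produced a negative branch length")
  out
}

# Construct the grafted clade as a phylo with tips ending at their stated
# ages; returns the clade with attr "root_age" = age of its basal node.
build_fossil_clade <- function(subtree, tip_ages, spacing) {
  if (is.character(subtree) && length(subtree) == 1L) {
    # single-tip graft: a degenerate "clade" of one branch
    age <- tip_ages[[subtree]]
    if (is.null(age) || is.na(age)) stop("no age for tip ", subtree)
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         edge.length = 0, tip.label = subtree, Nnode = 1L),
                    class = "phylo")
    attr(tr, "root_age") <- age
    return(tr)
  }
  tr <- subtree
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in subtree")
  miss <- setdiff(tr$tip.label, names(tip_ages))
  if (length(miss)) stop("missing tip ages for: ", paste(miss, collapse = ", "))
  n <- ape::Ntip(tr)
  age <- numeric(n + tr$Nnode)
  age[seq_len(n)] <- tip_ages[tr$tip.label]
  # postorder: children before parents; node age = max(child ages) + spacing
  ord <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; c <- ord$edge[k, 2L]
    age[p] <- max(age[p], age[c] + spacing)
  }
  el <- numeric(nrow(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    el[k] <- age[tr$edge[k, 1L]] - age[tr$edge[k, 2L]]
    if (el[k] < 0) stop("tip ages inconsistent with topology: negative branch")
  }
  tr$edge.length <- el
  attr(tr, "root_age") <- age[n + 1L]
  tr
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j in Ma;
#' the diagonal holds root-to-tip depths.  This is the expected trait
#' covariance (up to the Brownian rate) under Brownian motion on the tree.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

#' Generalised-least-squares (phylogenetic) mean
#'
#' The GLS intercept a = (1' C^-1 1)^-1 1' C^-1 Y per trait column: the
#' estimate of the root state under Brownian motion.  On a star tree this
#' reduces to the arithmetic column mean.
#'
#' @param C Phylogenetic covariance (tips x tips).
#' @param Y Numeric vector or matrix, rows aligned with C.
#' @return Numeric vector, one entry per trait column.
#' @export
phylo_gls_mean <- function(C, Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(C)) stop("C and Y tip counts differ")
  Cinv <- tryCatch(solve(C), error = function(e) {
    stop(sprintf("singular phylogenetic covariance (condition number %.3g)",
                 kappa(C)))
  })
  one <- rep(1, nrow(C))
  drop((crossprod(one, Cinv %*% Y)) / drop(crossprod(one, Cinv %*% one)))
}
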