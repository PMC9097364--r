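test_that("read_newick parses, validates and round-trips", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(diag(phylo_vcv(tr))), c(1, 1))

  expect_error(read_newick("(A:1,A:1);"), "duplicate")
  expect_error(read_newick("(A:1,B:1);", file = "x"), "exactly one")
  expect_error(read_newick("(A,B);"), "branch lengths")

  # round-trip oracle on a generated 64-tip tree
  tr64 <- simulate_tree(64, seed = 19)
  back <- read_newick(write_newick(tr64))
  expect_true(ape::all.equal.phylo(tr64, back, use.edge.length = TRUE,
                                   tolerance = 1e-9))
})

test_that("scale_tree_depth rescales linearly and preserves ratios", {
  tr <- simulate_tree(16, depth_ma = 47, seed = 2)
  sc <- scale_tree_depth(tr, 94)
  expect_equal(tree_depth(sc), 94, tolerance = 1e-9)
  expect_equal(sc$edge.length, tr$edge.length * 2, tolerance = 1e-12)

  same <- scale_tree_depth(tr, tree_depth(tr))
  expect_equal(same$edge.length, tr$edge.length, tolerance = 1e-12)

  sc131 <- scale_tree_depth(tr, 131)
  expect_equal(tree_depth(sc131), 131, tolerance = 1e-9)
  r <- sc131$edge.length / tr$edge.length
  expect_lt(diff(range(r)), 1e-12)   # one common factor

  zero <- tr; zero$edge.length[] <- 0
  expect_error(scale_tree_depth(zero, 94), "zero depth")
})

test_that("graft_clade places fossil tips at stated ages", {
  host <- simulate_tree(8, depth_ma = 94, seed = 1)
  g <- graft_clade(host, "root", "fossil", stem_age = 131,
                   tip_ages = c(fossil = 122))
  i <- which(g$tip.label == "fossil")
  expect_equal(g$edge.length[g$edge[, 2] == i], 9, tolerance = 1e-9)
  expect_equal(tree_depth(g), 131, tolerance = 1e-9)

  # polytomy of two equal-age tips -> equal terminal branches
  sub <- read_newick("(F1:1,F2:1):0;")
  g2 <- graft_clade(host, "root", sub, stem_age = 131,
                    tip_ages = c(F1 = 120, F2 = 120))
  bl <- vapply(c("F1", "F2"), function(nm)
    g2$edge.length[g2$edge[, 2] == which(g2$tip.label == nm)], numeric(1))
  expect_equal(bl[["F1"]], bl[["F2"]], tolerance = 1e-9)

  expect_error(graft_clade(host, "root", "f", stem_age = 100,
                           tip_ages = c(f = 122)), "older")
})

test_that("six-tip fossil-family graft satisfies all age constraints", {
  # topology: early-diverging genus (two morphotypes) sister to the rest;
  # a three-way polytomy inside; oldest tip at 122 Ma
  host <- simulate_tree(12, depth_ma = 94, seed = 4)
  sub <- read_newick(
    "((LongipteryxLT:1,LongipteryxST:1):1,(Shanweiniao:1,(Longirostravis:1,Rapaxavis:1,Shengjingornis:1):1):1):0;")
  ages <- c(LongipteryxLT = 120, LongipteryxST = 120, Shanweiniao = 122,
            Longirostravis = 120, Rapaxavis = 120, Shengjingornis = 120)
  g <- graft_clade(host, "root", sub, stem_age = 131, tip_ages = ages)
  expect_true(all(g$edge.length > 0))
  dep <- tree_depth(g)
  tipdep <- diag(phylo_vcv(g))
  # extant tips reach the present (131); fossil tips end at their ages
  expect_equal(unname(tipdep[host$tip.label]), rep(131, 12), tolerance = 1e-9)
  expect_equal(unname(tipdep[names(ages)]), 131 - unname(ages),
               tolerance = 1e-6)
})

test_that("phylo_vcv matches the brute-force path-walk oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2):0;")
  C <- phylo_vcv(tr)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)

  star <- ape::stree(6, "star"); star$edge.length <- rep(3, 6)
  Cs <- phylo_vcv(star)
  expect_equal(Cs, diag(3, 6, 6), ignore_attr = TRUE)

  for (s in 1:10) {
    n <- sample(4:64, 1)
    tr <- simulate_tree(n, seed = 100 + s)
    expect_equal(phylo_vcv(tr), brute_vcv(tr), tolerance = 1e-9)
  }
})

test_that("phylo_gls_mean matches the GLS oracle", {
  star <- ape::stree(5, "star"); star$edge.length <- rep(1, 5)
  y <- c(1, 2, 3, 4, 10)
  expect_equal(phylo_gls_mean(phylo_vcv(star), y), mean(y))

  tr <- simulate_tree(12, seed = 7)
  C <- phylo_vcv(tr)
  expect_equal(phylo_gls_mean(C, rep(3.5, 12)), 3.5)

  Y <- simulate_bm_traits(tr, n_traits = 2, seed = 8)
  # direct GLS intercept oracle
  one <- rep(1, 12)
  a <- solve(t(one) %*% solve(C) %*% one) %*% t(one) %*% solve(C) %*% Y
  expect_equal(phylo_gls_mean(C, Y), drop(a), tolerance = 1e-10)
})
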