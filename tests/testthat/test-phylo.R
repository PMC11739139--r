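# Distance matrices, NJ/BIONJ exactness, midpoint rooting, bootstrap,
# clade queries and Robinson-Foulds distances.

test_that("distance matrices are symmetric and match per-pair k2p calls", {
  set.seed(5)
  base <- randomSequence(600)
  msa <- setNames(vapply(1:6, function(i)
    evolveSequence(base, runif(1, 0.01, 0.15), 2), character(1)),
    paste0("t", 1:6))
  D <- distanceMatrix(msa)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], k2p(msa[[i]], msa[[j]])$d, tolerance = 1e-12)
  # identical triplet -> zeros
  D0 <- distanceMatrix(setNames(rep(base, 3), c("a", "b", "c")))
  expect_true(all(D0 == 0))
  expect_error(distanceMatrix(msa[1:2]), "at least 3")
})

test_that("saturated pairs are flagged and refused by tree building", {
  msa <- c(a = strrep("A", 30), b = strrep("G", 30), c = strrep("A", 30))
  D <- distanceMatrix(msa)
  expect_true(is.na(D["a", "b"]))
  expect_error(njTree(D), "saturated")
})

test_that("NJ recovers 4-taxon additive trees exactly", {
  case <- randomAdditiveCase(4, seed = 8)
  for (variant in c("classic", "bionj")) {
    tr <- njTree(case$D, variant)
    expect_equal(rfDistance(tr, case$tree), 0)
    m1 <- edgeLengthMap(tr); m2 <- edgeLengthMap(case$tree)
    for (k in names(m2)) expect_equal(m1[[k]], m2[[k]], tolerance = 1e-9)
  }
})

test_that("3-taxon distances follow the closed three-point formulas", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D, "classic")
  # a = (d_ab + d_ac - d_bc)/2 etc.
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["a"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(el["b"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(el["c"]), 0.4, tolerance = 1e-12)
})

test_that("NJ matches exhaustive minimum-RSS search on additive matrices", {
  for (sd in 1:5) {
    case <- randomAdditiveCase(6, seed = 100 + sd)
    oracle <- exhaustiveTreeSearch(case$D)
    tr <- njTree(case$D, "bionj")
    expect_equal(rfDistance(tr, oracle), 0)
    m1 <- edgeLengthMap(tr); m2 <- edgeLengthMap(oracle)
    for (k in names(m2)) expect_equal(m1[[k]], m2[[k]], tolerance = 1e-9)
  }
})

test_that("midpoint rooting balances the longest tip-to-tip path", {
  two <- ape::read.tree(text = "(a:1,b:3);")
  r <- midpointRoot(two)
  depths <- ape::node.depth.edgelength(r)[1:2]
  expect_equal(unname(depths), c(2, 2))
  # idempotence on topology
  tr <- simulateHostTree(10, 0.2, seed = 31)
  r1 <- midpointRoot(tr)
  r2 <- midpointRoot(r1)
  expect_equal(rfDistance(r1, r2), 0)
  # max root-to-tip depth equals half the diameter
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(max(ape::node.depth.edgelength(r1)[seq_along(r1$tip.label)]),
               max(coph) / 2, tolerance = 1e-9)
  zero <- ape::read.tree(text = "(a:0,b:0);")
  expect_error(midpointRoot(zero), "ambiguous")
})

test_that("bootstrap supports are deterministic, bounded and order-invariant", {
  set.seed(6)
  base <- randomSequence(400)
  msa <- setNames(vapply(1:6, function(i)
    evolveSequence(base, 0.08, 2), character(1)), paste0("t", 1:6))
  b1 <- bootstrapSupport(msa, n = 50, seed = 3)
  b2 <- bootstrapSupport(msa, n = 50, seed = 3)
  expect_identical(b1$node.label, b2$node.label)
  sup <- b1$node.label[!is.na(b1$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  # single replicate: supports all 0 or 100
  bone <- bootstrapSupport(msa, n = 1, seed = 4)
  s1 <- bone$node.label[!is.na(bone$node.label)]
  expect_true(all(s1 %in% c(0, 100)))
  # taxon input order does not change split supports
  perm <- rev(msa)
  bperm <- bootstrapSupport(perm, n = 50, seed = 3)
  for (tipset in list(c("t1", "t2"), c("t5", "t6"))) {
    expect_equal(cladeSupport(b1, tipset), cladeSupport(bperm, tipset))
  }
})

test_that("strong unique synapomorphies give 100% support everywhere", {
  # alignment constructed from a fixed tree: every edge marked by 30
  # private columns; zero homoplasy
  tips <- paste0("t", 1:6)
  base <- randomSequence(400, seed = 91)
  seqs <- setNames(rep(base, 6), tips)
  rotate <- function(ch) chartr("ACGT", "CGTA", ch)
  groups <- list(c("t1", "t2"), c("t1", "t2", "t3"), c("t5", "t6"),
                 c("t4", "t5", "t6"), "t1", "t2", "t3", "t4", "t5", "t6")
  pos <- 1
  for (g in groups) {
    for (nm in g)
      substr(seqs[nm], pos, pos + 19) <-
        rotate(substr(seqs[nm], pos, pos + 19))
    pos <- pos + 20
  }
  bt <- bootstrapSupport(seqs, n = 50, seed = 9)
  expect_true(all(bt$node.label[!is.na(bt$node.label)] == 100))
})

test_that("monophyly, sister groups and RF distances behave canonically", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:1,e:1):2);")
  expect_true(isMonophyleticClade(tr, c("a", "b")))
  expect_false(isMonophyleticClade(tr, c("a", "c", "d")))
  expect_true(isMonophyleticClade(tr, c("a", "b", "c", "d", "e")))
  expect_error(isMonophyleticClade(tr, "zz"), "unknown")
  expect_setequal(sisterGroup(tr, c("a", "b")), "c")
  expect_setequal(sisterGroup(tr, "c"), c("a", "b"))
  expect_error(sisterGroup(tr, c("a", "b", "c", "d", "e")),
               class = "retroHTT_undefined")
  expect_equal(rfDistance(tr, tr), 0)
  # one NNI move changes RF by 2 on 5 tips
  tr2 <- ape::read.tree(text = "(((a:1,c:1):1,b:2):1,(d:1,e:1):2);")
  expect_equal(rfDistance(tr, tr2), 2)
  # cross-check against an established implementation
  set.seed(12)
  for (i in 1:10) {
    x <- ape::rtree(8); y <- ape::rtree(8)
    expect_equal(rfDistance(x, y),
                 as.numeric(phangorn::RF.dist(x, y)))
  }
})

test_that("in-package NJ agrees topologically with the reference implementation", {
  set.seed(44)
  for (i in 1:5) {
    base <- randomSequence(800)
    msa <- setNames(vapply(1:7, function(k)
      evolveSequence(base, runif(1, 0.02, 0.12), 2), character(1)),
      paste0("t", 1:7))
    D <- distanceMatrix(msa)
    expect_equal(rfDistance(njTree(D, "classic"), ape::nj(D)), 0)
    expect_equal(rfDistance(njTree(D, "bionj"), ape::bionj(D)), 0)
  }
})
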