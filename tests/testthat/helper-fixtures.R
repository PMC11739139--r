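# Shared in-code fixtures: tiny queries, depth profiles and tree oracles.

tinyQuery <- function(id = "TyT", ltr = 60, internal = 400, seed = 11) {
  randomQuery(id, ltr_len = ltr, internal_len = internal, seed = seed)
}

flatProfile <- function(depth, baseline = 30, qid = "q", fold = baseline) {
  new("DepthProfile", query_id = qid, depth = as.numeric(depth),
      baseline_depth = baseline, fold_coverage_original = fold)
}

pileupFromCounts <- function(counts, region = c(0, nrow(counts)),
                             qid = "q") {
  storage.mode(counts) <- "integer"
  colnames(counts) <- c("A", "C", "G", "T")
  new("PileupCounts", query_id = qid, counts = counts, region = region)
}

# least-squares branch-length fit of a fixed topology to a distance matrix;
# independent oracle for distance-tree inference
lsFitTree <- function(topo, D) {
  topo <- ape::unroot(topo)
  tips <- topo$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  E <- nrow(topo$edge)
  A <- matrix(0, nrow(pairs), E)
  for (e in seq_len(E)) {
    child <- topo$edge[e, 2]
    below <- if (child <= n) tips[child]
             else ape::extract.clade(topo, child)$tip.label
    inA <- tips[pairs[, 1]] %in% below
    inB <- tips[pairs[, 2]] %in% below
    A[, e] <- as.numeric(xor(inA, inB))
  }
  d <- D[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- qr.solve(A, d)
  topo$edge.length <- fit
  list(tree = topo, rss = sum((A %*% fit - d)^2))
}

# exhaustive minimum-RSS topology search over all unrooted topologies
exhaustiveTreeSearch <- function(D) {
  tips <- rownames(D)
  topos <- phangorn::allTrees(length(tips), tip.label = tips)
  fits <- lapply(topos, lsFitTree, D = D)
  best <- which.min(vapply(fits, `[[`, numeric(1), "rss"))
  fits[[best]]$tree
}

# map of bipartition -> branch length (trivial tip splits keyed by tip name)
edgeLengthMap <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n <- length(tips)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- if (child <= n) tree$tip.label[child]
             else ape::extract.clade(tree, child)$tip.label
    side <- below
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    out[[key]] <- tree$edge.length[e]
  }
  out
}

# random additive distance matrix from a random tree; returns both
randomAdditiveCase <- function(n = 6, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}
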