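## Distance-based phylogenetics: K2P distance matrices, NJ/BIONJ trees with
## negative-branch clamping, midpoint rooting, seeded bootstrap supports,
## clade queries and Robinson-Foulds distances.

## K2P distance matrix on an integer alignment matrix (rows = sequences).
## Vectorized via one-hot cross-products: for all pairs at once,
##   n_sites = V V', same = sum_b B_b B_b', ts = A G' + G A' + C T' + T C'.
.k2pMatrixInt <- function(m) {
  oh <- lapply(1:4, function(b) {
    x <- m == b
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  V <- !is.na(m)
  storage.mode(V) <- "double"
  N <- tcrossprod(V)
  same <- Reduce(`+`, lapply(oh, tcrossprod))
  X <- tcrossprod(oh[[1]], oh[[3]])  # A vs G
  Y <- tcrossprod(oh[[2]], oh[[4]])  # C vs T
  ts <- X + t(X) + Y + t(Y)
  P <- ts / N
  Q <- (N - same - ts) / N
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  # saturated entries produce NaN logs; they are flagged as NA below
  D <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  D[w1 <= 0 | w2 <= 0 | N == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' K2P distance matrix from a multiple sequence alignment
#'
#' Pairwise K2P distances under pairwise deletion.  Saturated pairs are
#' reported as NA (flagged, not silently numeric); \code{\link{njTree}}
#' refuses matrices containing them.
#'
#' @param msa named character vector of aligned sequences (>= 3).
#' @return symmetric numeric matrix with zero diagonal, attribute
#'   \code{model = "K2P"}.
#' @export
distanceMatrix <- function(msa) {
  if (length(msa) < 3) stop("at least 3 sequences are required")
  D <- .k2pMatrixInt(.alnInt(msa))
  attr(D, "model") <- "K2P"
  D
}

## clamp negative NJ branch-length estimates to zero, transferring the
## deficit to the adjacent (parent-side) branch so path lengths are
## approximately preserved
.clampNegativeEdges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (i in neg) {
    deficit <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    parent_edge <- which(tree$edge[, 2] == tree$edge[i, 1])
    if (length(parent_edge))
      tree$edge.length[parent_edge] <-
        max(0, tree$edge.length[parent_edge] + deficit)
  }
  tree
}

#' Neighbor-joining / BIONJ tree from a distance matrix
#'
#' Double-precision agglomerative distance-tree inference.  The
#' \code{"classic"} variant is Saitou-Nei neighbor joining; \code{"bionj"}
#' additionally propagates distance-estimate variances and weights each
#' matrix reduction by the variance-minimizing factor (Gascuel's reduction
#' formula).  For additive input distances both variants reproduce the
#' generating topology and branch lengths exactly.  Agglomeration ties are
#' broken deterministically in favour of the lexicographically smallest
#' taxon-label pair.  Negative branch-length estimates (possible on
#' non-additive input) are clamped to zero with the deficit transferred to
#' the adjacent branch.
#'
#' @param dm symmetric distance matrix (from \code{\link{distanceMatrix}}).
#' @param variant \code{"bionj"} (default) or \code{"classic"}.
#' @return unrooted \code{phylo}.
#' @export
njTree <- function(dm, variant = c("bionj", "classic")) {
  variant <- match.arg(variant)
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("at least 3 taxa are required")
  if (anyNA(dm))
    stop("distance matrix contains saturated (NA) pairs; remove or ",
         "re-estimate the affected sequences before tree building")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ## process in lexicographic label order so tie-breaking is deterministic
  o <- order(labels)
  D <- unname(dm[o, o])
  V <- D                      # variance matrix (bionj); unused for classic
  frag <- labels[o]           # newick fragment per active cluster
  key <- labels[o]            # lexicographic tie-break key per cluster
  fmt <- function(x) sprintf("%.17g", x)
  while (length(frag) > 3L) {
    m <- length(frag)
    R <- rowSums(D)
    ## Q criterion; pick the strictly smallest, scanning pairs in
    ## lexicographic key order
    best <- NULL; bestQ <- Inf
    ord <- order(key)
    for (ii in seq_len(m - 1L)) {
      for (jj in (ii + 1L):m) {
        a <- ord[ii]; b <- ord[jj]
        Qab <- (m - 2) * D[a, b] - R[a] - R[b]
        thresh <- if (is.finite(bestQ))
          bestQ - 1e-14 * max(1, abs(bestQ)) else Inf
        if (Qab < thresh) {
          bestQ <- Qab; best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    La <- D[a, b] / 2 + (R[a] - R[b]) / (2 * (m - 2))
    Lb <- D[a, b] - La
    lambda <- 0.5
    if (variant == "bionj" && D[a, b] > 0 && V[a, b] > 0) {
      ks <- setdiff(seq_len(m), c(a, b))
      lambda <- 0.5 + sum(V[b, ks] - V[a, ks]) / (2 * (m - 2) * V[a, b])
      lambda <- min(1, max(0, lambda))
    }
    newfrag <- paste0("(", frag[a], ":", fmt(La), ",", frag[b], ":",
                      fmt(Lb), ")")
    newkey <- min(key[a], key[b])
    ks <- setdiff(seq_len(m), c(a, b))
    dnew <- lambda * (D[a, ks] - La) + (1 - lambda) * (D[b, ks] - Lb)
    vnew <- lambda * V[a, ks] + (1 - lambda) * V[b, ks] -
      lambda * (1 - lambda) * V[a, b]
    keep <- ks
    D2 <- D[keep, keep, drop = FALSE]
    V2 <- V[keep, keep, drop = FALSE]
    D <- rbind(cbind(D2, dnew), c(dnew, 0))
    V <- rbind(cbind(V2, vnew), c(vnew, 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }
  ## resolve the final three clusters with the three-point formulas
  L1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  L2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  L3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(L1), ",", frag[2], ":", fmt(L2),
                ",", frag[3], ":", fmt(L3), ");")
  tr <- ape::read.tree(text = nwk)
  .clampNegativeEdges(tr)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @return rooted \code{phylo}.
#' @export
midpointRoot <- function(tree) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    stop("midpoint root is ambiguous: tree has no positive branch lengths")
  out <- phangorn::midpoint(tree)
  # bootstrap annotations survive rerooting (splits are root-invariant)
  attr(out, "boot_trees") <- attr(tree, "boot_trees")
  attr(out, "boot_splits") <- attr(tree, "boot_splits")
  out
}

## canonical nontrivial bipartitions of an (un)rooted tree as strings.
## Each split is represented by the side NOT containing the reference tip
## (first tip in alphabetical order), tips sorted and joined.
.bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    k <- length(side)
    if (k >= 2 && k <= length(labs) - 2)
      out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' trees (same tip sets required).
#'
#' @param t1,t2 \code{phylo} objects over the same tips.
#' @return non-negative integer.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same tip set")
  b1 <- .bipartitions(ape::unroot(t1))
  b2 <- .bipartitions(ape::unroot(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Test whether a tip set is monophyletic
#'
#' @param tree a \code{phylo}.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
isMonophyleticClade <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label))
    stop("unknown tip(s): ", paste(setdiff(tips, tree$tip.label),
                                   collapse = ", "))
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Sister group of a clade
#'
#' Tips of the other daughter lineage of the clade's parent node in a
#' rooted tree.  Requesting the sister of the full tip set raises a
#' distinct error.
#'
#' @param tree a rooted \code{phylo}.
#' @param tips tip labels of the (monophyletic) focal clade.
#' @return character vector of sister tips.
#' @export
sisterGroup <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label))
    stop("unknown tip(s): ", paste(setdiff(tips, tree$tip.label),
                                   collapse = ", "))
  if (length(tips) == length(tree$tip.label))
    stop(structure(class = c("retroHTT_undefined", "error", "condition"),
                   list(message = "sister group undefined for the full tip set",
                        call = sys.call(-1))))
  node <- if (length(tips) == 1L) which(tree$tip.label == tips)
          else ape::getMRCA(tree, tips)
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(parent))
    stop(structure(class = c("retroHTT_undefined", "error", "condition"),
                   list(message = "clade is the root: sister group undefined",
                        call = sys.call(-1))))
  kids <- tree$edge[tree$edge[, 1] == parent, 2]
  sib <- setdiff(kids, node)
  unlist(lapply(sib, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  }))
}

#' Bootstrap supports for a distance tree
#'
#' Builds the tree from the full alignment, then \code{n} replicates by
#' resampling alignment columns with replacement (seeded; resampling acts on
#' column indices only, so supports are invariant to taxon input order).
#' Support for each internal edge is the percentage of replicate trees
#' containing its bipartition.  In replicates, saturated pairs are imputed
#' as twice the largest finite distance so a replicate tree always exists.
#'
#' @param msa named character vector of aligned sequences (>= 4).
#' @param n number of replicates (default 100).
#' @param seed integer seed.
#' @param variant passed to \code{\link{njTree}}.
#' @return the full-alignment \code{phylo} with \code{node.label} set to
#'   support percentages (NA for the root) and attribute
#'   \code{"boot_trees"} holding the replicate trees.
#' @export
bootstrapSupport <- function(msa, n = 100, seed = 1,
                             variant = c("bionj", "classic")) {
  variant <- match.arg(variant)
  if (length(msa) < 4) stop("at least 4 sequences are required")
  m <- .alnInt(msa)
  dm0 <- .k2pMatrixInt(m)
  if (anyNA(dm0))
    stop("alignment contains saturated pairs; cannot bootstrap")
  orig <- njTree(dm0, variant)
  L <- ncol(m)
  boots <- withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      idx <- sample.int(L, L, replace = TRUE)
      db <- .k2pMatrixInt(m[, idx, drop = FALSE])
      if (anyNA(db)) {
        mx <- max(db, na.rm = TRUE)
        db[is.na(db)] <- 2 * max(mx, 1e-6)
      }
      njTree(db, variant)
    })
  })
  boot_sets <- lapply(boots, .bipartitions)
  ## map each internal edge's bipartition to a support percentage
  tips <- sort(orig$tip.label)
  ref <- tips[1]
  Ntip <- length(orig$tip.label)
  node_lab <- rep(NA_real_, orig$Nnode)
  for (node in (Ntip + 1L):(Ntip + orig$Nnode)) {
    has_parent <- any(orig$edge[, 2] == node)
    if (!has_parent) next  # root of the (arbitrary) representation
    clade <- ape::extract.clade(orig, node)$tip.label
    side <- clade
    if (ref %in% side) side <- setdiff(orig$tip.label, side)
    k <- length(side)
    if (k < 2 || k > Ntip - 2) next  # trivial split
    key <- paste(sort(side), collapse = "\r")
    node_lab[node - Ntip] <-
      100 * mean(vapply(boot_sets, function(b) key %in% b, logical(1)))
  }
  orig$node.label <- node_lab
  attr(orig, "boot_trees") <- boots
  attr(orig, "boot_splits") <- boot_sets
  orig
}

#' Bootstrap support for an arbitrary tip bipartition
#'
#' Percentage of the bootstrap replicate trees (attached by
#' \code{\link{bootstrapSupport}}) that contain the split separating
#' \code{tips} from the rest.
#'
#' @param tree output of \code{\link{bootstrapSupport}}.
#' @param tips tip labels on one side of the split.
#' @return support percentage in [0, 100].
#' @export
cladeSupport <- function(tree, tips) {
  splits <- attr(tree, "boot_splits")
  if (is.null(splits)) {
    boots <- attr(tree, "boot_trees")
    if (is.null(boots)) stop("tree carries no bootstrap replicates")
    splits <- lapply(boots, .bipartitions)
  }
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  side <- tips
  if (ref %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "\r")
  100 * mean(vapply(splits, function(b) key %in% b, logical(1)))
}
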