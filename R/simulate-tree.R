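#' Simulate a rooted host strain tree
#'
#' Generates a random rooted binary tree over strain identifiers, optionally
#' structured into lineages (clades of strains standing in for
#' populations/species).  With \code{n_lineages} set, a lineage backbone tree
#' is drawn first and each lineage tip is replaced by a shallow within-lineage
#' subtree, giving the deep-split / shallow-tip structure typical of
#' multi-population strain panels.  Branch lengths are in expected
#' substitutions per site.
#'
#' @param n_strains number of strains (tips), at least 2.
#' @param depth_scale scale of backbone branch lengths (expected
#'   substitutions/site; default 0.1).
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @param n_lineages optional number of lineages; strains are distributed as
#'   evenly as possible.  Default NULL: unstructured tree, each strain is its
#'   own lineage.
#' @param within_scale within-lineage branch-length scale as a fraction of
#'   \code{depth_scale} (default 0.15).
#' @return an ape \code{phylo} with tip labels \code{s01, s02, ...}, node
#'   labels \code{n1, n2, ...} and an attribute \code{"lineages"}: a named
#'   character vector mapping strain to lineage label.
#' @examples
#' tr <- simulateHostTree(8, 0.1, seed = 42, n_lineages = 4)
#' attr(tr, "lineages")
#' @export
simulateHostTree <- function(n_strains, depth_scale = 0.1, seed = 1,
                             n_lineages = NULL, within_scale = 0.15) {
  if (n_strains < 2) stop("n_strains must be at least 2")
  if (depth_scale <= 0) stop("depth_scale must be positive")
  withr_seed(seed, {
    if (is.null(n_lineages) || n_lineages >= n_strains) {
      tr <- ape::rtree(n_strains,
                       tip.label = sprintf("s%02d", seq_len(n_strains)))
      tr$edge.length <- tr$edge.length * depth_scale
      lin <- setNames(tr$tip.label, tr$tip.label)
    } else {
      if (n_lineages < 2) stop("n_lineages must be at least 2")
      sizes <- rep(n_strains %/% n_lineages, n_lineages)
      extra <- n_strains %% n_lineages
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      backbone <- ape::rtree(n_lineages,
                             tip.label = paste0("L", seq_len(n_lineages)))
      backbone$edge.length <- (0.5 + backbone$edge.length) * depth_scale
      nxt <- 1L
      lin <- character(0)
      for (j in seq_len(n_lineages)) {
        labs <- sprintf("s%02d", nxt:(nxt + sizes[j] - 1L))
        nxt <- nxt + sizes[j]
        lin[labs] <- paste0("L", j)
        if (sizes[j] == 1L) {
          backbone$tip.label[backbone$tip.label == paste0("L", j)] <- labs
        } else {
          sub <- ape::rtree(sizes[j], tip.label = labs)
          sub$edge.length <- sub$edge.length * depth_scale * within_scale
          where <- which(backbone$tip.label == paste0("L", j))
          backbone <- ape::bind.tree(backbone, sub, where = where)
        }
      }
      tr <- backbone
    }
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
    attr(tr, "lineages") <- lin[sort(names(lin))]
    tr
  })
}

#' Lineage labels of a simulated host tree
#' @param tree a tree from \code{\link{simulateHostTree}}.
#' @export
hostLineages <- function(tree) {
  lin <- attr(tree, "lineages")
  if (is.null(lin)) setNames(tree$tip.label, tree$tip.label) else lin
}
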