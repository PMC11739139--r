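## Horizontal-transfer flags from three classical lines of evidence:
## host/TE tree incongruence, unexpectedly high cross-species TE similarity,
## and patchy presence/absence across host lineages.

## mean patristic distance between two species' strains on the host tree
.speciesHostDist <- function(host_coph, host_species_of, sp1, sp2) {
  s1 <- names(host_species_of)[host_species_of == sp1]
  s2 <- names(host_species_of)[host_species_of == sp2]
  s1 <- intersect(s1, rownames(host_coph))
  s2 <- intersect(s2, rownames(host_coph))
  if (!length(s1) || !length(s2)) return(NA_real_)
  mean(host_coph[s1, s2, drop = FALSE])
}

## expected sister species of `sp` on the host tree: species of the sister
## group of sp's clade, walking rootward until one with TEs in the pool is
## found (topological, not distance-based)
.expectedSisterSpecies <- function(host_tree, host_species_of, sp,
                                   species_pool) {
  tips_sp <- intersect(names(host_species_of)[host_species_of == sp],
                       host_tree$tip.label)
  if (!length(tips_sp)) return(character(0))
  Ntip <- length(host_tree$tip.label)
  node <- if (length(tips_sp) == 1L) which(host_tree$tip.label == tips_sp)
          else ape::getMRCA(host_tree, tips_sp)
  cladeTips <- function(nd) {
    if (nd <= Ntip) host_tree$tip.label[nd]
    else ape::extract.clade(host_tree, nd)$tip.label
  }
  repeat {
    pe <- which(host_tree$edge[, 2] == node)
    if (!length(pe)) return(character(0))
    parent <- host_tree$edge[pe, 1]
    sis_tips <- setdiff(cladeTips(parent), cladeTips(node))
    cand <- setdiff(intersect(unique(host_species_of[sis_tips]),
                              species_pool), sp)
    if (length(cand)) return(cand)
    node <- parent
  }
}

## maximal same-species clades of a species' tips in a rooted tree
.maximalSpeciesClades <- function(tree, tips) {
  if (length(tips) == 1L) return(list(tips))
  if (isMonophyleticClade(tree, tips)) return(list(tips))
  ## greedy: walk tips, grow each into the largest clade containing only
  ## focal tips
  remaining <- tips
  out <- list()
  Ntip <- length(tree$tip.label)
  while (length(remaining)) {
    t0 <- remaining[1]
    node <- which(tree$tip.label == t0)
    best <- t0
    repeat {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      if (!length(parent)) break
      clade <- ape::extract.clade(tree, parent)$tip.label
      if (all(clade %in% tips)) {
        best <- clade
        node <- parent
      } else break
    }
    out[[length(out) + 1L]] <- best
    remaining <- setdiff(remaining, best)
  }
  out
}

#' Flag candidate horizontal transposon transfer events
#'
#' Emits evidence flags by comparing a TE element tree with the host strain
#' tree:
#' \describe{
#'   \item{incongruence}{a well-supported species-specific TE clade whose
#'     sister species in the TE tree shares no member with the species'
#'     topological sister group on the host tree (walking rootward past
#'     species without TEs).  When a TE distance matrix is supplied, the
#'     clade must additionally be closer to its observed sister than the
#'     host divergence allows (distance below host divergence divided by
#'     \code{host_excess}); this guards against hidden paralogy, where loss
#'     of a paralog lineage in the true sister species reshuffles sisters
#'     without any transfer.}
#'   \item{excess_similarity}{a species pair whose minimum cross-species TE
#'     distance is below \code{sim_ratio} times the median within-species TE
#'     distance \emph{and} below the species pair's host divergence by at
#'     least the factor \code{host_excess} (under vertical descent, TE
#'     divergence is bounded below by host divergence when substitution
#'     rates are comparable, so a TE pair much closer than its hosts points
#'     to transfer).}
#'   \item{patchy_distribution}{a subfamily whose present strains are
#'     non-monophyletic on the host tree with at least
#'     \code{min_absent_inside} absent strains nested inside the presence
#'     clade.}
#' }
#'
#' @param te_tree rooted \code{phylo} of TE elements (ideally from
#'   \code{\link{bootstrapSupport}} + \code{\link{midpointRoot}}; supports
#'   are looked up with \code{\link{cladeSupport}} when bootstrap replicates
#'   are attached, otherwise assumed 100).
#' @param host_tree rooted \code{phylo} of strains.
#' @param species_of named character vector: TE tip label -> species.
#' @param host_species_of named character vector: host tip (strain) ->
#'   species.
#' @param te_dm TE distance matrix over TE tips (for excess-similarity;
#'   optional).
#' @param presence_table data.frame with columns strain, subfamily, present
#'   (for patchy-distribution; optional).
#' @param min_support minimum bootstrap support for incongruence evidence
#'   (default 70).
#' @param sim_ratio excess-similarity ratio threshold (default 0.5).
#' @param host_excess required host-divergence/TE-distance margin for
#'   excess-similarity evidence (default 1.5).
#' @param rate_scale TE/host substitution-rate ratio used to scale host
#'   divergences (default 1).
#' @param min_absent_inside patchiness threshold (default 2).
#' @return data.frame of flags: evidence, focus, partner, support, value,
#'   detail (zero rows when nothing is flagged).
#' @export
httFlag <- function(te_tree, host_tree, species_of, host_species_of,
                    te_dm = NULL, presence_table = NULL, min_support = 70,
                    sim_ratio = 0.5, host_excess = 1.5, rate_scale = 1,
                    min_absent_inside = 2) {
  if (!all(te_tree$tip.label %in% names(species_of)))
    stop("unmappable TE tips: ",
         paste(setdiff(te_tree$tip.label, names(species_of)), collapse = ", "))
  if (!all(host_tree$tip.label %in% names(host_species_of)))
    stop("unmappable host tips: ",
         paste(setdiff(host_tree$tip.label, names(host_species_of)),
               collapse = ", "))
  flags <- list()
  addFlag <- function(evidence, focus, partner, support, value, detail) {
    flags[[length(flags) + 1L]] <<- data.frame(
      evidence = evidence, focus = focus, partner = partner,
      support = support, value = value, detail = detail,
      stringsAsFactors = FALSE)
  }
  host_coph <- ape::cophenetic.phylo(host_tree) * rate_scale
  te_species <- species_of[te_tree$tip.label]
  species_in_te <- unique(te_species)
  has_boot <- !is.null(attr(te_tree, "boot_splits")) ||
    !is.null(attr(te_tree, "boot_trees"))

  ## --- (a) incongruence ---------------------------------------------------
  if (length(species_in_te) >= 3) {
    for (sp in species_in_te) {
      tipsX <- te_tree$tip.label[te_species == sp]
      expected <- .expectedSisterSpecies(host_tree, host_species_of, sp,
                                         species_in_te)
      if (!length(expected)) next
      clades <- .maximalSpeciesClades(te_tree, tipsX)
      for (cl in clades) {
        if (length(cl) == length(te_tree$tip.label)) next
        sis <- tryCatch(sisterGroup(te_tree, cl), error = function(e) NULL)
        if (is.null(sis)) next
        sis_species <- unique(species_of[sis])
        if (identical(sort(sis_species), sp)) next  # same-species sister
        sup <- if (has_boot) {
          grp <- union(cl, sis)
          if (length(grp) >= length(te_tree$tip.label)) 100
          else cladeSupport(te_tree, grp)
        } else 100
        if (sup < min_support) next
        if (!is.null(te_dm)) {
          sis_in_dm <- intersect(sis, rownames(te_dm))
          cl_in_dm <- intersect(cl, rownames(te_dm))
          if (length(sis_in_dm) && length(cl_in_dm)) {
            dmin_cs <- min(te_dm[cl_in_dm, sis_in_dm, drop = FALSE],
                           na.rm = TRUE)
            hostd_cs <- min(vapply(unique(species_of[sis_in_dm]), function(o)
              .speciesHostDist(host_coph, host_species_of, sp, o),
              numeric(1)), na.rm = TRUE)
            # paralogy guard: vertical clades sit at (or beyond) host
            # divergence from any sister; transferred clades sit well below
            if (!is.finite(hostd_cs) || dmin_cs >= hostd_cs / host_excess)
              next
          }
        }
        if (!length(intersect(sis_species, expected)) && !(sp %in% sis_species))
          addFlag("incongruence", sp,
                  paste(sort(sis_species), collapse = "+"), sup, NA_real_,
                  sprintf("clade{%s} sister %s, host sister %s",
                          paste(cl, collapse = ","),
                          paste(sort(sis_species), collapse = "+"),
                          paste(sort(expected), collapse = "+")))
      }
    }
  }

  ## --- (b) excess similarity ----------------------------------------------
  if (!is.null(te_dm) && length(species_in_te) >= 2) {
    within <- c()
    for (sp in species_in_te) {
      tipsX <- intersect(te_tree$tip.label[te_species == sp], rownames(te_dm))
      if (length(tipsX) >= 2) {
        sub <- te_dm[tipsX, tipsX]
        within <- c(within, sub[upper.tri(sub)])
      }
    }
    med_within <- if (length(within)) stats::median(within, na.rm = TRUE)
                  else NA_real_
    if (!is.na(med_within) && med_within > 0) {
      pairs <- utils::combn(species_in_te, 2, simplify = FALSE)
      for (pr in pairs) {
        t1 <- intersect(te_tree$tip.label[te_species == pr[1]],
                        rownames(te_dm))
        t2 <- intersect(te_tree$tip.label[te_species == pr[2]],
                        rownames(te_dm))
        if (!length(t1) || !length(t2)) next
        dmin <- min(te_dm[t1, t2, drop = FALSE], na.rm = TRUE)
        hostd <- .speciesHostDist(host_coph, host_species_of, pr[1], pr[2])
        if (is.na(hostd)) next
        if (dmin < sim_ratio * med_within && hostd > host_excess * dmin)
          addFlag("excess_similarity", pr[1], pr[2], NA_real_,
                  dmin / med_within,
                  sprintf("min cross-species d=%.4g, median within d=%.4g, host divergence=%.4g",
                          dmin, med_within, hostd))
      }
    }
  }

  ## --- (c) patchy distribution --------------------------------------------
  if (!is.null(presence_table) && nrow(presence_table)) {
    for (sf in unique(presence_table$subfamily)) {
      pt <- presence_table[presence_table$subfamily == sf, , drop = FALSE]
      pres <- intersect(pt$strain[pt$present], host_tree$tip.label)
      abs_ <- intersect(pt$strain[!pt$present], host_tree$tip.label)
      if (length(pres) < 2 || !length(abs_)) next
      if (isMonophyleticClade(host_tree, pres)) next
      mrca <- ape::getMRCA(host_tree, pres)
      inside <- ape::extract.clade(host_tree, mrca)$tip.label
      absent_inside <- intersect(abs_, inside)
      if (length(absent_inside) >= min_absent_inside)
        addFlag("patchy_distribution", sf,
                paste(sort(absent_inside), collapse = "+"), NA_real_,
                length(absent_inside),
                sprintf("%d/%d strains absent inside presence clade",
                        length(absent_inside), length(inside)))
    }
  }

  if (length(flags)) do.call(rbind, flags) else
    data.frame(evidence = character(0), focus = character(0),
               partner = character(0), support = numeric(0),
               value = numeric(0), detail = character(0),
               stringsAsFactors = FALSE)
}
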