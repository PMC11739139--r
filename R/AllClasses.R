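#' @import methods
#' @importFrom stats median rbinom rpois runif rnorm setNames
#' @importFrom utils read.table write.table head tail
NULL

#' TE query model: a subfamily reference partitioned into LTR/internal regions
#'
#' A \code{TEQueryModel} holds one subfamily reference sequence (e.g. a
#' canonical Ty4-like or Tsu4-like element) together with the coordinates of
#' its 5' LTR, internal (gag/pol) region and 3' LTR.  All copy-number,
#' annotation and consensus coordinates in the package are expressed on this
#' query.  Regions are 0-based half-open and must tile the query exactly.
#'
#' @slot query_id single character identifier.
#' @slot sequence character scalar over A/C/G/T (the query sequence).
#' @slot regions named list with elements \code{ltr5}, \code{internal},
#'   \code{ltr3}, each \code{c(start, end)} 0-based half-open.
#'
#' @examples
#' q <- randomQuery("TyX", ltr_len = 50, internal_len = 200, seed = 1)
#' queryRegions(q)$internal
#' @export
setClass("TEQueryModel",
  representation(
    query_id = "character",
    sequence = "character",
    regions  = "list"
  )
)

setValidity("TEQueryModel", function(object) {
  msg <- character()
  if (length(object@query_id) != 1L || !nzchar(object@query_id))
    msg <- c(msg, "query_id must be a single non-empty string")
  if (length(object@sequence) != 1L)
    msg <- c(msg, "sequence must be a single string")
  if (grepl("[^ACGT]", object@sequence))
    msg <- c(msg, "sequence must contain only A/C/G/T")
  need <- c("ltr5", "internal", "ltr3")
  if (!identical(sort(names(object@regions)), sort(need))) {
    msg <- c(msg, "regions must be named ltr5, internal, ltr3")
  } else {
    L <- nchar(object@sequence)
    r <- object@regions
    ok <- vapply(r, function(x) length(x) == 2L && x[1] >= 0 && x[2] <= L &&
                   x[1] < x[2], logical(1))
    if (!all(ok)) {
      msg <- c(msg, "each region must be c(start, end), 0 <= start < end <= length")
    } else {
      # regions must tile the query: ltr5, internal, ltr3 contiguous
      if (!(r$ltr5[1] == 0 && r$ltr5[2] == r$internal[1] &&
            r$internal[2] == r$ltr3[1] && r$ltr3[2] == L))
        msg <- c(msg, "regions must tile the query as ltr5|internal|ltr3")
      l5 <- r$ltr5[2] - r$ltr5[1]; l3 <- r$ltr3[2] - r$ltr3[1]
      if (abs(l5 - l3) > 0.2 * max(l5, l3))
        msg <- c(msg, "ltr5 and ltr3 lengths must be within 20% of each other")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-base read depth over a TE query
#'
#' Raw material for copy-number and breadth estimation: an integer depth for
#' every query position plus the single-copy baseline depth of the genome the
#' reads came from.
#'
#' @slot query_id query the depths are expressed on.
#' @slot depth integer vector, one entry per query base (0-based positions).
#' @slot baseline_depth positive scalar: mean depth over single-copy sequence.
#' @slot fold_coverage_original sequencing fold coverage before any
#'   down-sampling (used by \code{\link{downsampleDepth}}).
#' @export
setClass("DepthProfile",
  representation(
    query_id = "character",
    depth = "numeric",
    baseline_depth = "numeric",
    fold_coverage_original = "numeric"
  )
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  if (any(object@depth < 0)) msg <- c(msg, "depth must be non-negative")
  if (length(object@baseline_depth) != 1L || object@baseline_depth <= 0)
    msg <- c(msg, "baseline_depth must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Filtered per-site base counts over a query region
#'
#' Base counts after mapping-quality and base-quality filtering, used by
#' \code{\link{majorityConsensus}}.  Row i holds the A/C/G/T counts at the
#' i-th position of the region the pileup covers.
#'
#' @slot query_id query identifier.
#' @slot counts integer matrix with columns A, C, G, T.
#' @slot region c(start, end), 0-based half-open interval of the query the
#'   rows correspond to.
#' @export
setClass("PileupCounts",
  representation(
    query_id = "character",
    counts = "matrix",
    region = "numeric"
  )
)

setValidity("PileupCounts", function(object) {
  msg <- character()
  if (!identical(colnames(object@counts), c("A", "C", "G", "T")))
    msg <- c(msg, "counts must have columns A, C, G, T")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@region) != 2L || object@region[1] >= object@region[2])
    msg <- c(msg, "region must be c(start, end) with start < end")
  else if (nrow(object@counts) != object@region[2] - object@region[1])
    msg <- c(msg, "counts must have one row per region position")
  if (length(msg)) msg else TRUE
})

#' Sliding-window divergence profile of a candidate against parent sequences
#'
#' Kimura 2-parameter distances between one candidate sequence and each of
#' several candidate parents, computed in sliding windows over alignment
#' columns.  Windows with too few comparable sites carry NA.
#'
#' @slot centers numeric vector of window centre columns (1-based, strictly
#'   increasing).
#' @slot d numeric matrix, one column per parent, one row per window.
#' @slot window window width in alignment columns.
#' @slot step step between window starts.
#' @export
setClass("DivergenceProfile",
  representation(
    centers = "numeric",
    d = "matrix",
    window = "numeric",
    step = "numeric"
  )
)

setValidity("DivergenceProfile", function(object) {
  msg <- character()
  if (object@window <= 0 || object@step <= 0)
    msg <- c(msg, "window and step must be positive")
  if (length(object@centers) != nrow(object@d))
    msg <- c(msg, "centers length must equal nrow(d)")
  if (length(object@centers) > 1 && any(diff(object@centers) <= 0))
    msg <- c(msg, "centers must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' A simulated TE family history with ground truth
#'
#' Container returned by \code{\link{simulateFamilyHistory}}: the host strain
#' tree, the per-strain element inventory with true structural class and
#' subfamily, the gap-free truth alignment of all element sequences, the
#' replay log of evolutionary events, and the query models used at the root.
#'
#' @slot tree ape \code{phylo} host strain tree (tips = strain ids).
#' @slot lineages named character vector mapping strain id to lineage label.
#' @slot elements data.frame, one row per surviving element copy per strain
#'   (columns: element_id, strain, subfamily, class, sequence, ancestry,
#'   origin).
#' @slot events data.frame event log (event, branch, time, element_id, detail).
#' @slot queries named list of \code{TEQueryModel}, one per subfamily.
#' @slot params list of simulation parameters as used.
#' @export
setClass("TySimulation",
  representation(
    tree = "ANY",
    lineages = "character",
    elements = "data.frame",
    events = "data.frame",
    queries = "list",
    params = "list"
  )
)

setValidity("TySimulation", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  need <- c("element_id", "strain", "subfamily", "class", "sequence")
  if (!all(need %in% names(object@elements)))
    msg <- c(msg, paste("elements must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@elements) &&
      !all(object@elements$class %in% c("FLE", "truncated", "solo_LTR")))
    msg <- c(msg, "element class must be FLE, truncated or solo_LTR")
  if (length(msg)) msg else TRUE
})

## -- show methods -----------------------------------------------------------

setMethod("show", "TEQueryModel", function(object) {
  r <- object@regions
  cat("TEQueryModel '", object@query_id, "' (", nchar(object@sequence),
      " bp)\n", sep = "")
  cat(sprintf("  ltr5: [%d,%d)  internal: [%d,%d)  ltr3: [%d,%d)\n",
              r$ltr5[1], r$ltr5[2], r$internal[1], r$internal[2],
              r$ltr3[1], r$ltr3[2]))
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile over '", object@query_id, "': ", length(object@depth),
      " positions, baseline ", signif(object@baseline_depth, 4), "x\n", sep = "")
})

setMethod("show", "PileupCounts", function(object) {
  cat("PileupCounts over '", object@query_id, "' [",
      object@region[1], ",", object@region[2], "), total depth ",
      sum(object@counts), "\n", sep = "")
})

setMethod("show", "DivergenceProfile", function(object) {
  cat("DivergenceProfile: ", length(object@centers), " windows (w=",
      object@window, ", s=", object@step, ") vs parents: ",
      paste(colnames(object@d), collapse = ", "), "\n", sep = "")
})

setMethod("show", "TySimulation", function(object) {
  cat("TySimulation: ", length(object@tree$tip.label), " strains, ",
      nrow(object@elements), " surviving elements, ",
      nrow(object@events), " events\n", sep = "")
  if (nrow(object@elements)) {
    tab <- table(object@elements$subfamily, object@elements$class)
    print(tab)
  }
})

## -- accessors --------------------------------------------------------------

#' @describeIn TEQueryModel region map accessor
#' @param x a TEQueryModel
#' @export
queryRegions <- function(x) {
  stopifnot(is(x, "TEQueryModel"))
  x@regions
}

#' @describeIn TEQueryModel sequence accessor
#' @export
querySequence <- function(x) {
  stopifnot(is(x, "TEQueryModel"))
  x@sequence
}

#' @describeIn TEQueryModel identifier accessor
#' @export
queryId <- function(x) {
  stopifnot(is(x, "TEQueryModel"))
  x@query_id
}

#' Depth vector of a DepthProfile
#' @param x a DepthProfile
#' @export
depthValues <- function(x) {
  stopifnot(is(x, "DepthProfile"))
  x@depth
}

#' Single-copy baseline depth of a DepthProfile
#' @param x a DepthProfile
#' @export
baselineDepth <- function(x) {
  stopifnot(is(x, "DepthProfile"))
  x@baseline_depth
}

#' Element inventory of a simulation
#' @param x a TySimulation
#' @export
simElements <- function(x) {
  stopifnot(is(x, "TySimulation"))
  x@elements
}

#' Event log of a simulation
#' @param x a TySimulation
#' @export
simEvents <- function(x) {
  stopifnot(is(x, "TySimulation"))
  x@events
}

#' Host strain tree of a simulation
#' @param x a TySimulation
#' @export
simTree <- function(x) {
  stopifnot(is(x, "TySimulation"))
  x@tree
}

#' Query models of a simulation
#' @param x a TySimulation
#' @export
simQueries <- function(x) {
  stopifnot(is(x, "TySimulation"))
  x@queries
}

#' Lineage labels of a simulation
#' @param x a TySimulation
#' @export
simLineages <- function(x) {
  stopifnot(is(x, "TySimulation"))
  x@lineages
}
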