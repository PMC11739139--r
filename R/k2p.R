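## Kimura 2-parameter divergence, sliding-window profiles and breakpoint
## inference. Alignments are named character vectors of equal-length strings
## (A/C/G/T plus N or '-' for missing); sites with a non-base in either
## sequence of a pair are excluded (pairwise deletion).

## core on integer codes; returns list(P, Q, d, n_sites, status)
.k2pInt <- function(ai, bi) {
  ok <- !is.na(ai) & !is.na(bi)
  n <- sum(ok)
  if (n == 0L)
    return(list(P = NA_real_, Q = NA_real_, d = NA_real_, n_sites = 0L,
                status = "no_sites"))
  a <- ai[ok]; b <- bi[ok]
  diff <- a != b
  # transitions: A<->G (codes 1,3), C<->T (codes 2,4): |a-b| == 2
  ts <- sum(diff & abs(a - b) == 2L)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(P = P, Q = Q, d = NA_real_, n_sites = n, status = "saturated"))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  list(P = P, Q = Q, d = d, n_sites = n, status = "ok")
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the transition proportion P, transversion proportion Q and the
#' K2P distance d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q) under pairwise
#' deletion: alignment columns where either sequence carries a gap or N are
#' excluded.  Saturated pairs (where a log argument is non-positive) and pairs
#' with zero comparable sites are not errors: they return \code{d = NA} with
#' \code{status} set to \code{"saturated"} or \code{"no_sites"} so callers can
#' handle them distinctly.
#'
#' @param seqA,seqB aligned sequences of equal length (character scalars).
#' @return a list of class \code{k2pResult} with elements \code{P}, \code{Q},
#'   \code{d}, \code{n_sites}, \code{status}.
#' @examples
#' a <- strrep("A", 20)
#' k2p(a, a)$d   # 0
#' @export
k2p <- function(seqA, seqB) {
  ai <- .seq2int(seqA); bi <- .seq2int(seqB)
  if (length(ai) != length(bi))
    stop("sequences must be aligned to equal length")
  res <- .k2pInt(ai, bi)
  class(res) <- "k2pResult"
  res
}

#' @export
print.k2pResult <- function(x, ...) {
  cat(sprintf("K2P: d=%s  P=%.4g Q=%.4g  (%d sites, %s)\n",
              ifelse(is.na(x$d), "NA", sprintf("%.6g", x$d)),
              x$P, x$Q, x$n_sites, x$status))
  invisible(x)
}

## alignment (named character vector) -> integer matrix rows = sequences
.alnInt <- function(aln) {
  if (is.matrix(aln)) {
    m <- matrix(match(aln, .BASES), nrow = nrow(aln),
                dimnames = dimnames(aln))
    return(m)
  }
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment sequences must have equal length")
  m <- matrix(NA_integer_, nrow = length(aln), ncol = L,
              dimnames = list(names(aln), NULL))
  for (i in seq_along(aln)) m[i, ] <- .seq2int(aln[[i]])
  m
}

#' Sliding-window K2P divergence of a candidate against candidate parents
#'
#' For each window of \code{w} alignment columns advanced by \code{s}, the
#' K2P distance between the candidate and every parent is computed over that
#' window.  Windows in which fewer than half the columns are comparable for a
#' parent (or that are saturated) yield \code{NA} for that parent.  Window
#' centres are reported as 1-based alignment column midpoints.
#'
#' @param candidate aligned candidate sequence (character scalar).
#' @param parents named character vector of aligned parent sequences.
#' @param w window size in alignment columns (default 50).
#' @param s step size in alignment columns (default 10).
#' @return a \linkS4class{DivergenceProfile}.
#' @export
slidingWindowDivergence <- function(candidate, parents, w = 50, s = 10) {
  if (is.null(names(parents)) || any(!nzchar(names(parents))))
    names(parents) <- paste0("parent", seq_along(parents))
  ci <- .seq2int(candidate)
  L <- length(ci)
  if (any(nchar(parents) != L))
    stop("candidate and parents must share the same alignment length")
  if (L < w) stop("alignment shorter than the window size")
  pint <- lapply(parents, .seq2int)
  starts <- seq(1L, L - w + 1L, by = s)
  centers <- starts + (w - 1) / 2
  d <- matrix(NA_real_, nrow = length(starts), ncol = length(parents),
              dimnames = list(NULL, names(parents)))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + w - 1L)
    cw <- ci[idx]
    for (j in seq_along(pint)) {
      r <- .k2pInt(cw, pint[[j]][idx])
      if (r$status == "ok" && r$n_sites >= w / 2) d[k, j] <- r$d
    }
  }
  new("DivergenceProfile", centers = centers, d = d, window = w, step = s)
}

#' Infer recombination breakpoints from a two-parent divergence profile
#'
#' Computes the per-window distance difference
#' \eqn{\Delta d = d(\mathrm{cand}, A) - d(\mathrm{cand}, B)} and calls a
#' breakpoint wherever the sign of \eqn{\Delta d} changes between two runs of
#' at least \code{min_seg} consecutive same-sign windows.  Windows with
#' missing values break runs, and no breakpoint is called across a gap of
#' missing evidence.  The breakpoint column is the midpoint between the
#' flanking window centres.
#'
#' Windows whose absolute difference falls below \code{min_delta_frac} times
#' the median absolute difference are treated as uninformative: they are
#' skipped without breaking a run (overlapping sliding windows make sign
#' noise near zero strongly autocorrelated, so a magnitude guard is needed
#' to avoid spurious short runs).
#'
#' @param profile a \linkS4class{DivergenceProfile} with exactly two parents.
#' @param min_seg minimum run length (windows) for a segment (default 3).
#' @param min_delta_frac uninformative-window threshold as a fraction of the
#'   median |delta d| (default 0.5).
#' @return a list of class \code{BreakpointCall} with elements
#'   \code{breakpoints} (numeric alignment columns), \code{segments}
#'   (data.frame: start_col, end_col, parent, confidence = mean |delta d|),
#'   and \code{status} (\code{"ok"} or \code{"no_call"}).
#' @export
inferBreakpoints <- function(profile, min_seg = 3, min_delta_frac = 0.5) {
  stopifnot(is(profile, "DivergenceProfile"))
  if (ncol(profile@d) != 2L)
    stop("breakpoint inference requires a profile with exactly 2 parents")
  dd_all <- profile@d[, 1] - profile@d[, 2]
  ## drop uninformative windows (ties and sub-threshold magnitudes) without
  ## breaking runs; windows missing a distance still break runs below
  thr <- min_delta_frac * stats::median(abs(dd_all), na.rm = TRUE)
  informative <- is.na(dd_all) | abs(dd_all) >= max(thr, .Machine$double.eps)
  centers_use <- profile@centers[informative]
  dd <- dd_all[informative]
  sgn <- sign(dd)                      # NA propagates (missing evidence)
  out <- list(breakpoints = numeric(0),
              segments = data.frame(start_col = numeric(0),
                                    end_col = numeric(0),
                                    parent = character(0),
                                    confidence = numeric(0),
                                    stringsAsFactors = FALSE),
              status = "no_call")
  class(out) <- "BreakpointCall"
  if (all(is.na(sgn))) return(out)
  # run-length encode; 0 stands for missing evidence and breaks runs
  state <- ifelse(is.na(sgn), 0, sgn)
  r <- rle(state)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  qualified <- which(r$values != 0 & r$lengths >= min_seg)
  if (!length(qualified)) return(out)
  parents <- colnames(profile@d)
  # assemble segments: consecutive qualified runs of the same sign merge;
  # a sign change yields a breakpoint unless a missing-evidence run (state 0)
  # separates the two qualified runs
  seg_first <- seg_last <- integer(0)   # run indices bounding each segment
  bps <- numeric(0)
  for (q in qualified) {
    if (length(seg_first) &&
        r$values[q] == r$values[seg_last[length(seg_last)]]) {
      seg_last[length(seg_last)] <- q
      next
    }
    if (length(seg_first)) {
      prev <- seg_last[length(seg_last)]
      between <- if (q > prev + 1L) r$values[(prev + 1L):(q - 1L)] else numeric(0)
      if (!any(between == 0))
        bps <- c(bps, (centers_use[run_end[prev]] +
                       centers_use[run_start[q]]) / 2)
    }
    seg_first <- c(seg_first, q)
    seg_last <- c(seg_last, q)
  }
  segs <- data.frame(
    start_col = centers_use[run_start[seg_first]],
    end_col = centers_use[run_end[seg_last]],
    parent = ifelse(r$values[seg_first] < 0, parents[1], parents[2]),
    confidence = mapply(function(a, b) {
      idx <- run_start[a]:run_end[b]
      mean(abs(dd[idx]), na.rm = TRUE)
    }, seg_first, seg_last),
    stringsAsFactors = FALSE
  )
  rownames(segs) <- NULL
  out$breakpoints <- bps
  out$segments <- segs
  out$status <- "ok"
  out
}

#' @export
print.BreakpointCall <- function(x, ...) {
  if (x$status != "ok") {
    cat("BreakpointCall: no call (insufficient evidence)\n")
    return(invisible(x))
  }
  cat("BreakpointCall:", length(x$breakpoints), "breakpoint(s)",
      if (length(x$breakpoints)) paste("at",
        paste(round(x$breakpoints, 1), collapse = ", ")) else "", "\n")
  print(x$segments)
  invisible(x)
}

#' Partition an alignment into named column intervals
#'
#' Column-exact slices of a multiple sequence alignment, e.g. the 5'/3'
#' segments flanking a recombination breakpoint.  Intervals are 1-based
#' inclusive alignment columns, must be ordered and non-overlapping.
#'
#' @param msa named character vector of aligned sequences.
#' @param spec named list of \code{c(first, last)} column intervals.
#' @return named list of sub-alignments (named character vectors).
#' @export
partitionAlignment <- function(msa, spec) {
  L <- unique(nchar(msa))
  if (length(L) != 1L) stop("alignment sequences must have equal length")
  iv <- do.call(rbind, spec)
  if (any(iv[, 1] > iv[, 2]) || any(iv[, 1] < 1) || any(iv[, 2] > L))
    stop("invalid partition spec: intervals must lie within the alignment")
  if (nrow(iv) > 1L) {
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)]))
      stop("invalid partition spec: intervals overlap")
  }
  lapply(spec, function(r) {
    vapply(msa, function(s) substr(s, r[1], r[2]), character(1))
  })
}

#' Map an alignment column to an ungapped sequence position
#'
#' @param alnseq one aligned sequence (may contain '-' gaps).
#' @param col 1-based alignment column.
#' @return 1-based position in the ungapped sequence, or NA if the column is
#'   a gap in this sequence.
#' @export
alignmentColumnToSeqPos <- function(alnseq, col) {
  ch <- strsplit(alnseq, "", fixed = TRUE)[[1]]
  stopifnot(col >= 1, col <= length(ch))
  if (ch[col] == "-") return(NA_integer_)
  sum(ch[seq_len(col)] != "-")
}
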