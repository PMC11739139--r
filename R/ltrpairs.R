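## De novo detection of candidate LTR pairs: seed-and-extend search for
## direct repeats at element-scale separation with target-site duplication
## and terminal-motif checks, mirroring the standard LTRharvest-style
## parameterization (repeat length 100-1000, start separation 1500-15000,
## identity >= 0.80, 5-bp TSD, tg...ca termini, best-overlap selection).

## ungapped X-drop extension of an exact seed pair at fixed offset.
## a, b: integer-coded sequence; (i, j) seed starts, k seed length.
## Returns extension c(left, right) beyond the seed.
.xdropExtend <- function(s, i, j, k, match = 2, mismatch = -2, xdrop = 10) {
  n <- length(s)
  # left
  best <- 0; cur <- 0; left <- 0
  step <- 1
  while (i - step >= 1 && j - step > i + k - 1) {
    cur <- cur + if (s[i - step] == s[j - step]) match else mismatch
    if (cur > best) { best <- cur; left <- step }
    if (best - cur > xdrop) break
    step <- step + 1
  }
  # right
  best <- 0; cur <- 0; right <- 0
  step <- 1
  while (j + k - 1 + step <= n && i + k - 1 + step < j) {
    cur <- cur + if (s[i + k - 1 + step] == s[j + k - 1 + step]) match else mismatch
    if (cur > best) { best <- cur; right <- step }
    if (best - cur > xdrop) break
    step <- step + 1
  }
  c(left, right)
}

## all offsets within `vic` at which both repeats carry the dinucleotide,
## ordered by increasing |offset|
.motifOffsets <- function(s, pos1, pos2, dinuc, vic) {
  n <- length(s)
  offs <- seq(-vic, vic)[order(abs(seq(-vic, vic)))]
  keep <- vapply(offs, function(off) {
    p1 <- pos1 + off; p2 <- pos2 + off
    p1 >= 1 && p2 + 1 <= n &&
      all(s[c(p1, p1 + 1)] == dinuc) && all(s[c(p2, p2 + 1)] == dinuc)
  }, logical(1))
  offs[keep]
}

.detectLTRPairsOne <- function(seq, min_len, max_len, min_dist, max_dist,
                               min_identity, tsd_len, motif, motif_required,
                               tsd_required, seed_len, vic = 30) {
  n <- nchar(seq)
  if (n < min_dist + min_len) return(NULL)
  s <- .seq2int(seq)
  subs <- substring(seq, 1:(n - seed_len + 1L), seed_len:n)
  dup <- duplicated(subs) | duplicated(subs, fromLast = TRUE)
  if (!any(dup)) return(NULL)
  pos_by_key <- split(which(dup), subs[dup])
  seeds <- list()  # list of c(i, j) with j - i in [min_dist, max_dist]
  for (ps in pos_by_key) {
    if (length(ps) > 25L) next  # low-complexity guard
    for (a in seq_len(length(ps) - 1L)) {
      for (b in (a + 1L):length(ps)) {
        D <- ps[b] - ps[a]
        if (D >= min_dist && D <= max_dist)
          seeds[[length(seeds) + 1L]] <- c(ps[a], ps[b])
      }
    }
  }
  if (!length(seeds)) return(NULL)
  sm <- unique(do.call(rbind, seeds))
  sm <- sm[order(sm[, 2] - sm[, 1], sm[, 1]), , drop = FALSE]
  cands <- list()
  done <- list()  # per offset: covered seed intervals
  for (r in seq_len(nrow(sm))) {
    i <- sm[r, 1]; j <- sm[r, 2]
    D <- j - i
    key <- as.character(D)
    skip <- FALSE
    for (iv in done[[key]]) {
      if (i >= iv[1] && i <= iv[2]) { skip <- TRUE; break }
    }
    if (skip) next
    ext <- .xdropExtend(s, i, j, seed_len)
    li <- i - ext[1]; ri <- i + seed_len - 1L + ext[2]
    done[[key]] <- c(done[[key]], list(c(li, ri)))
    lj <- li + D; rj <- ri + D
    ## refine boundaries to the terminal motif within a small vicinity
    ## (ungapped extension can overshoot the true repeat ends by chance);
    ## when several motif anchors exist, prefer the one consistent with a
    ## target-site duplication
    m_start <- .seq2int(toupper(substr(motif, 1, 2)))
    m_end <- .seq2int(toupper(substr(motif, 3, 4)))
    o1s <- .motifOffsets(s, li, lj, m_start, vic)
    o2s <- .motifOffsets(s, ri - 1L, rj - 1L, m_end, vic)
    has_motif <- length(o1s) > 0 && length(o2s) > 0
    if (motif_required && !has_motif) next
    if (has_motif) {
      pick <- c(o1s[1], o2s[1])
      tsdAt <- function(o1, o2) {
        a <- li + o1; d <- rj + o2
        a - tsd_len >= 1L && d + tsd_len <= n &&
          all(s[(a - tsd_len):(a - 1L)] == s[(d + 1L):(d + tsd_len)])
      }
      found_tsd <- FALSE
      for (o1 in o1s) {
        for (o2 in o2s) {
          if (tsdAt(o1, o2)) { pick <- c(o1, o2); found_tsd <- TRUE; break }
        }
        if (found_tsd) break
      }
      li <- li + pick[1]; lj <- lj + pick[1]
      ri <- ri + pick[2]; rj <- rj + pick[2]
    }
    replen <- ri - li + 1L
    if (replen < min_len || replen > max_len) next
    ident <- mean(s[li:ri] == s[lj:rj])
    if (ident < min_identity) next
    ## TSD: tsd_len bases before left repeat == tsd_len after right repeat
    has_tsd <- li - tsd_len >= 1L && rj + tsd_len <= n &&
      substr(seq, li - tsd_len, li - 1L) ==
        substr(seq, rj + 1L, rj + tsd_len)
    if (tsd_required && !has_tsd) next
    cands[[length(cands) + 1L]] <- data.frame(
      left_start = li, left_end = ri, right_start = lj, right_end = rj,
      repeat_len = replen, identity = ident,
      spacer = lj - ri - 1L, tsd = has_tsd, motif = has_motif,
      span_start = li, span_end = rj,
      score = replen * ident, stringsAsFactors = FALSE)
  }
  if (!length(cands)) return(NULL)
  cd <- do.call(rbind, cands)
  cd <- cd[order(-cd$score), , drop = FALSE]
  ## best-overlap selection: greedily keep non-overlapping spans
  keep <- logical(nrow(cd))
  for (r in seq_len(nrow(cd))) {
    ok <- TRUE
    for (r2 in which(keep)) {
      if (cd$span_start[r] <= cd$span_end[r2] &&
          cd$span_end[r] >= cd$span_start[r2]) { ok <- FALSE; break }
    }
    keep[r] <- ok
  }
  cd <- cd[keep, , drop = FALSE]
  cd[order(cd$span_start), , drop = FALSE]
}

#' Detect candidate LTR pairs de novo in genome sequence
#'
#' Seed-and-extend search for direct repeats satisfying LTR-structure
#' bounds: repeat length within \code{[min_len, max_len]}, distance between
#' repeat starts within \code{[min_dist, max_dist]}, ungapped identity of at
#' least \code{min_identity}, a \code{tsd_len}-bp target-site duplication
#' flanking the pair, and the terminal motif (\code{tg...ca} on each repeat).
#' Overlapping candidates are resolved best-first by score
#' (length x identity).
#'
#' @param genome named character vector of contig sequences (or one scalar).
#' @param min_len,max_len repeat length bounds (defaults 100, 1000).
#' @param min_dist,max_dist bounds on distance between repeat starts
#'   (defaults 1500, 15000).
#' @param min_identity minimum repeat identity (default 0.80).
#' @param tsd_len target-site duplication length (default 5).
#' @param motif terminal motif (default \code{"tgca"}: repeats start tg, end
#'   ca).
#' @param motif_required,tsd_required require motif / TSD (defaults TRUE).
#' @param seed_len exact seed length for the initial match (default 16).
#' @return data.frame of candidates with 1-based inclusive coordinates:
#'   seqname, left_start, left_end, right_start, right_end, repeat_len,
#'   identity, spacer, tsd, motif, span_start, span_end.
#' @export
detectLTRPairs <- function(genome, min_len = 100, max_len = 1000,
                           min_dist = 1500, max_dist = 15000,
                           min_identity = 0.80, tsd_len = 5,
                           motif = "tgca", motif_required = TRUE,
                           tsd_required = TRUE, seed_len = 16) {
  if (!length(genome) || any(!nzchar(genome))) stop("genome must be non-empty")
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  out <- list()
  for (cn in names(genome)) {
    cd <- .detectLTRPairsOne(genome[[cn]], min_len, max_len, min_dist,
                             max_dist, min_identity, tsd_len, motif,
                             motif_required, tsd_required, seed_len)
    if (!is.null(cd) && nrow(cd)) {
      cd$seqname <- cn
      out[[length(out) + 1L]] <- cd
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[, c("seqname", setdiff(names(res), "seqname"))]
  } else {
    data.frame(seqname = character(0), left_start = integer(0),
               left_end = integer(0), right_start = integer(0),
               right_end = integer(0), repeat_len = integer(0),
               identity = numeric(0), spacer = integer(0),
               tsd = logical(0), motif = logical(0),
               span_start = integer(0), span_end = integer(0),
               score = numeric(0), stringsAsFactors = FALSE)
  }
}

#' Rescue divergent full-length elements using structural evidence
#'
#' Elements classified as truncated solely because they diverge from the
#' homology query are promoted to FLE when (a) their span reciprocally
#' overlaps a de novo LTR-pair candidate span by at least
#' \code{min_recip_overlap}, and (b) they belong to a group of at least
#' \code{min_count} such elements with pairwise sequence identity of at
#' least \code{min_mutual_identity}, dispersed over at least two distinct
#' target sequences.  This mirrors the recovery of a highly diverged but
#' active subfamily that a divergence-limited query fails to annotate as
#' full length.
#'
#' @param elements annotated elements (\code{\link{annotateElements}}
#'   output).
#' @param candidates \code{\link{detectLTRPairs}} output.
#' @param genome named character vector of contig sequences (for pairwise
#'   identity of element sequences).
#' @param min_mutual_identity minimum pairwise identity within a group
#'   (default 0.9).
#' @param min_count minimum group size (default 3).
#' @param min_recip_overlap minimum reciprocal span overlap with a candidate
#'   (default 0.8).
#' @return \code{elements} with promoted rows reclassified to FLE and a new
#'   logical column \code{rescued}.
#' @export
rescueDivergentFLE <- function(elements, candidates, genome,
                               min_mutual_identity = 0.9, min_count = 3,
                               min_recip_overlap = 0.8) {
  elements$rescued <- FALSE
  tr <- which(elements$class == "truncated")
  if (!length(tr) || !nrow(candidates)) return(elements)
  ## (a) reciprocal overlap with a candidate span
  overlaps <- vapply(tr, function(i) {
    e <- elements[i, ]
    cd <- candidates[candidates$seqname == e$target_seq, , drop = FALSE]
    for (r in seq_len(nrow(cd))) {
      # candidate span 1-based inclusive -> 0-based half-open
      cs <- cd$span_start[r] - 1; ce <- cd$span_end[r]
      ov <- max(0, min(e$end, ce) - max(e$start, cs))
      if (ov >= min_recip_overlap * (e$end - e$start) &&
          ov >= min_recip_overlap * (ce - cs)) return(TRUE)
    }
    FALSE
  }, logical(1))
  tr <- tr[overlaps]
  if (length(tr) < min_count) return(elements)
  ## (b) mutual-identity groups, dispersed over >= 2 target sequences
  seqs <- vapply(tr, function(i) {
    e <- elements[i, ]
    sq <- substr(genome[[e$target_seq]], e$start + 1L, e$end)
    if (e$strand == "-") .revcomp(sq) else sq
  }, character(1))
  m <- length(tr)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      pid <- if (nchar(seqs[i]) == nchar(seqs[j])) .identity(seqs[i], seqs[j])
      else {
        aln <- Biostrings::pairwiseAlignment(seqs[i], seqs[j],
                                             type = "global")
        Biostrings::pid(aln) / 100
      }
      adj[i, j] <- adj[j, i] <- !is.na(pid) && pid >= min_mutual_identity
    }
  }
  ## single-linkage components
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) {
      for (j in which(adj[i, ])) {
        if (comp[j] != comp[i]) {
          comp[pmax(comp[i], comp[j]) == comp] <-
            min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  for (cc in unique(comp)) {
    members <- tr[comp == cc]
    if (length(members) >= min_count &&
        length(unique(elements$target_seq[members])) >= 2L) {
      elements$class[members] <- "FLE"
      elements$rescued[members] <- TRUE
    }
  }
  elements
}
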