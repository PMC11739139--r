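## Read-evidence simulation: per-base depth over a TE query and filtered
## base-count pileups, produced by sampling uniform read start positions and
## projecting reads that overlap embedded TE copies onto query coordinates
## through the truth homology map (no read alignment is performed).

#' @importFrom IRanges IRanges coverage
NULL

## per-contig coverage Rle list for one strain's contigs
.strainCoverage <- function(fasta, strain, fold_coverage, read_len) {
  contigs <- grep(paste0("^", strain, "_c"), names(fasta), value = TRUE)
  covs <- list()
  for (cn in contigs) {
    len <- nchar(fasta[[cn]])
    n_reads <- rpois(1, fold_coverage * len / read_len)
    starts <- sample.int(len - read_len + 1L, n_reads, replace = TRUE)
    covs[[cn]] <- IRanges::coverage(IRanges::IRanges(starts, width = read_len),
                                    width = len)
  }
  covs
}

## project element-locus coverage onto query coordinates; both-LTR depth is
## collapsed onto the 5' LTR frame (mirrors the separate-LTR-query
## convention of coverage-based TE pipelines)
.projectDepth <- function(covs, bed_strain, query, collapse_ltr = TRUE) {
  regs <- queryRegions(query)
  qlen <- regs$ltr3[2]
  ltr_len <- regs$ltr5[2]
  depth <- numeric(qlen)
  for (i in seq_len(nrow(bed_strain))) {
    b <- bed_strain[i, ]
    cov <- as.integer(covs[[b$seqname]][(b$start + 1L):b$end])
    if (b$strand == "-") cov <- rev(cov)
    qpos <- (b$q_start + 1L):b$q_end   # 1-based query positions
    depth[qpos] <- depth[qpos] + cov
  }
  if (collapse_ltr) {
    # fold 3' LTR depth onto the 5' LTR interval
    i5 <- (regs$ltr5[1] + 1L):regs$ltr5[2]
    i3 <- (regs$ltr3[1] + 1L):regs$ltr3[2]
    depth[i5] <- depth[i5] + depth[i3]
    depth[i3] <- 0
  }
  depth
}

## mean background (single-copy) depth across a strain's contigs
.baselineDepth <- function(covs, bed_all) {
  tot <- 0; n <- 0
  for (cn in names(covs)) {
    v <- as.numeric(covs[[cn]])
    mask <- rep(TRUE, length(v))
    rows <- bed_all[bed_all$seqname == cn, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      mask[(rows$start[i] + 1L):rows$end[i]] <- FALSE
    tot <- tot + sum(v[mask]); n <- n + sum(mask)
  }
  tot / n
}

#' Simulate read depth and base-count evidence for one strain
#'
#' Samples uniform-start reads over the strain's contigs at the stated fold
#' coverage and projects reads overlapping embedded TE copies onto query
#' coordinates via the truth homology map, yielding a per-base
#' \linkS4class{DepthProfile} plus a \linkS4class{PileupCounts} over the
#' internal region with symmetric base-call errors at rate \code{err}.  Depth
#' over both LTRs is collapsed onto the 5' LTR frame, so the LTR interval
#' depth counts LTR copies (a full-length element contributes 2).  The
#' baseline is the mean depth over non-element background.
#'
#' @param run output of \code{\link{emitGenomes}}.
#' @param sim the \linkS4class{TySimulation} the run was emitted from (or an
#'   element data.frame); needed for element query intervals and sequences.
#' @param strain strain id.
#' @param query \linkS4class{TEQueryModel} to profile against.
#' @param fold_coverage sequencing depth (default 30).
#' @param read_len read length (default 100).
#' @param err per-base error probability in [0, 0.5) (default 0.01).
#' @param seed integer seed.
#' @return list with \code{depth} (DepthProfile) and \code{pileup}
#'   (PileupCounts over the internal region).
#' @export
simulateReadEvidence <- function(run, sim, strain, query, fold_coverage = 30,
                                 read_len = 100, err = 0.01, seed = 1) {
  if (fold_coverage <= 0) stop("fold_coverage must be positive")
  if (err < 0 || err >= 0.5) stop("err must lie in [0, 0.5)")
  el <- if (is(sim, "TySimulation")) simElements(sim) else sim
  withr_seed(seed, {
    covs <- .strainCoverage(run$fasta, strain, fold_coverage, read_len)
    bed_all <- run$bed[run$bed$strain == strain, , drop = FALSE]
    bed_q <- bed_all[bed_all$subfamily == queryId(query), , drop = FALSE]
    # attach retained query intervals from the inventory
    if (nrow(bed_q)) {
      m <- match(paste(bed_q$name, bed_q$strain),
                 paste(el$element_id, el$strain))
      bed_q$q_start <- el$q_start[m]
      bed_q$q_end <- el$q_end[m]
    }
    depth <- .projectDepth(covs, bed_q, query)
    baseline <- .baselineDepth(covs, bed_all)
    dp <- new("DepthProfile", query_id = queryId(query),
              depth = as.numeric(depth), baseline_depth = max(baseline, 1e-9),
              fold_coverage_original = fold_coverage)

    ## pileup over the internal region
    regs <- queryRegions(query)
    iv <- regs$internal
    counts <- matrix(0L, nrow = iv[2] - iv[1], ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    if (nrow(bed_q)) {
      m2 <- match(paste(bed_q$name, bed_q$strain),
                  paste(el$element_id, el$strain))
      for (i in seq_len(nrow(bed_q))) {
        qs <- bed_q$q_start[i]; qe <- bed_q$q_end[i]
        ov_s <- max(qs, iv[1]); ov_e <- min(qe, iv[2])
        if (ov_s >= ov_e) next
        cov <- as.integer(covs[[bed_q$seqname[i]]][
          (bed_q$start[i] + 1L):bed_q$end[i]])
        if (bed_q$strand[i] == "-") cov <- rev(cov)
        # coverage indexed by element-local position (query pos - qs)
        loc <- (ov_s - qs + 1L):(ov_e - qs)
        dep <- cov[loc]
        base <- .seq2int(el$sequence[m2[i]])[loc]
        row0 <- ov_s - iv[1]           # 0-based row offset into counts
        n_err <- rbinom(length(dep), dep, err)
        n_ok <- dep - n_err
        rows <- row0 + seq_along(dep)
        idx_ok <- cbind(rows, base)
        counts[idx_ok] <- counts[idx_ok] + n_ok
        we <- which(n_err > 0)
        for (j in we) {
          alt <- sample(setdiff(1:4, base[j]), n_err[j], replace = TRUE)
          for (a in alt) counts[rows[j], a] <- counts[rows[j], a] + 1L
        }
      }
    }
    pu <- new("PileupCounts", query_id = queryId(query), counts = counts,
              region = iv)
    list(depth = dp, pileup = pu)
  })
}

#' Simulate a per-base depth profile for one strain
#'
#' Convenience wrapper around \code{\link{simulateReadEvidence}} returning
#' only the \linkS4class{DepthProfile}.
#'
#' @inheritParams simulateReadEvidence
#' @export
simulateDepth <- function(run, sim, strain, query, fold_coverage = 30,
                          read_len = 100, seed = 1) {
  simulateReadEvidence(run, sim, strain, query, fold_coverage = fold_coverage,
                       read_len = read_len, err = 0, seed = seed)$depth
}

#' Emit a homology hit table for an emitted genome run
#'
#' One hit row per embedded element against its subfamily query (chimeric
#' elements are reported against their second, backbone parent query), with
#' target coordinates, strand, query interval and percent divergence computed
#' from the truth.  With probability \code{frag_prob} an element's hit is
#' split into two collinear fragments separated by a short gap in both target
#' and query coordinates, to exercise defragmentation.
#'
#' @param run output of \code{\link{emitGenomes}}.
#' @param sim the \linkS4class{TySimulation} (or element data.frame).
#' @param queries named list of \linkS4class{TEQueryModel}.
#' @param frag_prob probability of splitting an element's hit (default 0).
#' @param seed integer seed.
#' @return data.frame of hits with 0-based half-open coordinates: columns
#'   score, pct_div, target_seq, t_start, t_end, strand, query_id, q_start,
#'   q_end.
#' @export
emitHitTable <- function(run, sim, queries = NULL, frag_prob = 0, seed = 1) {
  if (frag_prob < 0 || frag_prob > 1) stop("frag_prob must lie in [0, 1]")
  el <- if (is(sim, "TySimulation")) simElements(sim) else sim
  if (is.null(queries) && is(sim, "TySimulation")) queries <- simQueries(sim)
  withr_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(run$bed))) {
      b <- run$bed[i, ]
      m <- which(el$element_id == b$name & el$strain == b$strain)[1]
      qid <- el$subfamily[m]
      if (!qid %in% names(queries)) {
        pars <- strsplit(el$parents[m], ",", fixed = TRUE)[[1]]
        qid <- if (length(pars) >= 2 && pars[2] %in% names(queries))
          pars[2] else names(queries)[1]
      }
      q <- queries[[qid]]
      qs <- el$q_start[m]; qe <- el$q_end[m]
      qseq <- substr(querySequence(q), qs + 1L, qe)
      div <- 100 * (1 - .identity(el$sequence[m], qseq))
      frags <- list(c(qs, qe))
      if (runif(1) < frag_prob && qe - qs > 400) {
        mid <- qs + round(runif(1, 0.3, 0.7) * (qe - qs))
        gap <- sample(40:120, 1)
        frags <- list(c(qs, mid - gap %/% 2), c(mid - gap %/% 2 + gap, qe))
      }
      for (fr in frags) {
        # map query fragment [a,b) to target coordinates
        a <- fr[1]; bb <- fr[2]
        if (b$strand == "+") {
          ts <- b$start + (a - qs); te <- b$start + (bb - qs)
        } else {
          ts <- b$start + (qe - bb); te <- b$start + (qe - a)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          score = round(2 * (bb - a)), pct_div = round(div, 2),
          target_seq = b$seqname, t_start = ts, t_end = te,
          strand = b$strand, query_id = qid, q_start = a, q_end = bb,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(score = numeric(0), pct_div = numeric(0),
                 target_seq = character(0), t_start = integer(0),
                 t_end = integer(0), strand = character(0),
                 query_id = character(0), q_start = integer(0),
                 q_end = integer(0), stringsAsFactors = FALSE)
  })
}
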