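## Small self-contained synthetic scenarios used to probe single stages:
## copy-number ladders (a strain with a known number of element copies) and
## labelled element sets for classification accuracy.

#' Simulate one strain carrying a known number of element copies
#'
#' Builds a strain whose genome contains exactly \code{k} full-length copies
#' of the query (each independently diverged from it by \code{divergence}),
#' emits the genome and simulates read evidence, for copy-number parameter
#' recovery experiments.
#'
#' @param k true copy number (>= 0).
#' @param query a \linkS4class{TEQueryModel}.
#' @param seed integer seed.
#' @param divergence per-copy divergence from the query (default 0.02).
#' @param fold_coverage,read_len,err read simulation settings.
#' @param background_length background length; default scales with k so the
#'   single-copy background always dominates.
#' @return list with \code{run}, \code{elements} (truth data.frame),
#'   \code{evidence} (list with \code{depth}, \code{pileup}).
#' @export
simulateStrainWithCopies <- function(k, query, seed = 1, divergence = 0.02,
                                     fold_coverage = 30, read_len = 100,
                                     err = 0, background_length = NULL) {
  stopifnot(k >= 0)
  if (is.null(background_length))
    background_length <- 30000 + k * 8000
  qlen <- nchar(querySequence(query))
  empty_elements <- data.frame(
    element_id = character(0), strain = character(0),
    subfamily = character(0), class = character(0), q_start = integer(0),
    q_end = integer(0), sequence = character(0), ancestry = character(0),
    origin = character(0), breakpoints = character(0),
    parents = character(0), stringsAsFactors = FALSE)
  withr_seed(seed, {
    elements <- if (k > 0) data.frame(
      element_id = sprintf("c%03d", seq_len(k)), strain = "s1",
      subfamily = queryId(query), class = "FLE",
      q_start = 0L, q_end = qlen,
      sequence = vapply(seq_len(k), function(i)
        evolveSequence(querySequence(query), divergence), character(1)),
      ancestry = "vertical", origin = "fixture", breakpoints = "",
      parents = "", stringsAsFactors = FALSE)
    else empty_elements
    run <- if (k > 0)
      emitGenomes(elements, background_length, seed = .subseed(seed, 11))
    else withr_seed(.subseed(seed, 11), list(
      fasta = setNames(
        c(randomSequence(background_length %/% 2),
          randomSequence(background_length %/% 2)),
        c("s1_c1", "s1_c2")),
      bed = data.frame(seqname = character(0), start = integer(0),
                       end = integer(0), name = character(0),
                       score = integer(0), strand = character(0),
                       strain = character(0), subfamily = character(0),
                       class = character(0), stringsAsFactors = FALSE),
      tsd_len = 5L))
    evidence <- simulateReadEvidence(run, elements, "s1", query,
                                     fold_coverage = fold_coverage,
                                     read_len = read_len, err = err,
                                     seed = .subseed(seed, 12))
    list(run = run, elements = elements, evidence = evidence)
  })
}

#' Simulate a labelled element set for classification experiments
#'
#' Generates \code{n} elements with known structural classes (FLE,
#' truncated, solo LTR) at divergences drawn uniformly from
#' \code{divergence_range}, embeds them in genomes (10 elements per strain)
#' and returns the truth inventory plus the emitted run.
#'
#' @param n number of elements.
#' @param queries named list of \linkS4class{TEQueryModel}; each element is
#'   assigned a random query.
#' @param seed integer seed.
#' @param divergence_range range of per-element divergence from the query
#'   (default c(0, 0.15)).
#' @param class_probs probabilities for FLE / truncated / solo_LTR (default
#'   c(0.5, 0.25, 0.25)).
#' @return list with \code{elements} (truth) and \code{run}.
#' @export
simulateElementSet <- function(n, queries, seed = 1,
                               divergence_range = c(0, 0.15),
                               class_probs = c(0.5, 0.25, 0.25)) {
  withr_seed(seed, {
    rows <- list()
    for (i in seq_len(n)) {
      qid <- sample(names(queries), 1)
      q <- queries[[qid]]
      regs <- queryRegions(q)
      qlen <- regs$ltr3[2]
      ltr_len <- regs$ltr5[2]
      d <- runif(1, divergence_range[1], divergence_range[2])
      full <- evolveSequence(querySequence(q), d)
      cls <- sample(c("FLE", "truncated", "solo_LTR"), 1, prob = class_probs)
      if (cls == "FLE") {
        qs <- 0L; qe <- qlen; sq <- full
      } else if (cls == "solo_LTR") {
        qs <- 0L; qe <- ltr_len; sq <- substr(full, 1, ltr_len)
      } else {
        cut <- round(runif(1, 0.25, 0.8) * qlen)
        if (runif(1) < 0.5) {
          qs <- cut; qe <- qlen; sq <- substr(full, cut + 1, qlen)
        } else {
          qs <- 0L; qe <- qlen - cut; sq <- substr(full, 1, qlen - cut)
        }
      }
      rows[[i]] <- data.frame(
        element_id = sprintf("x%04d", i),
        strain = sprintf("t%02d", 1L + (i - 1L) %/% 10L),
        subfamily = qid, class = cls, q_start = qs, q_end = qe,
        sequence = sq, ancestry = "vertical", origin = "fixture",
        breakpoints = "", parents = "", stringsAsFactors = FALSE)
    }
    elements <- do.call(rbind, rows)
    run <- emitGenomes(elements, background_length = 60000,
                       seed = .subseed(seed, 21), n_contigs = 2)
    list(elements = elements, run = run)
  })
}
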