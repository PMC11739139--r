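## Embedding simulated elements into random host background sequence.

#' Embed simulated elements into per-strain genome sequences
#'
#' Each strain's surviving elements are inserted at unique, non-overlapping
#' loci in i.i.d. random background sequence split across \code{n_contigs}
#' contigs, with a target-site duplication flanking every insertion and a
#' random recorded strand (minus-strand elements are reverse complemented).
#' The returned BED intervals (0-based, half-open) delimit the embedded
#' element exactly (TSD excluded).
#'
#' @param x a \linkS4class{TySimulation}, or an element data.frame in the
#'   same shape as \code{simElements()} output.
#' @param background_length total background length per strain (must exceed
#'   the strain's summed element length).
#' @param seed integer seed.
#' @param n_contigs contigs per strain (default 2).
#' @param tsd_len target-site duplication length (default 5).
#' @param min_gap minimum background gap between insertions (default 500).
#' @return list with \code{fasta}: named character vector of contig
#'   sequences (\code{<strain>_c<k>}), \code{bed}: data.frame with columns
#'   seqname, start, end, name (element_id), score, strand, strain,
#'   subfamily, class, and \code{tsd_len}.
#' @export
emitGenomes <- function(x, background_length = 60000, seed = 1,
                        n_contigs = 2, tsd_len = 5, min_gap = 500) {
  el <- if (is(x, "TySimulation")) simElements(x) else x
  stopifnot(is.data.frame(el))
  withr_seed(seed, {
    fasta <- character(0)
    bed_rows <- list()
    for (s in unique(el$strain)) {
      es <- el[el$strain == s, , drop = FALSE]
      elen <- nchar(es$sequence)
      if (sum(elen) >= background_length)
        stop("background_length must exceed total element length for strain ", s)
      clen <- rep(background_length %/% n_contigs, n_contigs)
      contig_names <- paste0(s, "_c", seq_len(n_contigs))
      assign_contig <- if (nrow(es))
        sample(rep_len(seq_len(n_contigs), nrow(es))) else integer(0)
      for (ci in seq_len(n_contigs)) {
        idx <- which(assign_contig == ci)
        bg <- .randomSeqInt(clen[ci])
        if (!length(idx)) {
          fasta[contig_names[ci]] <- .int2seq(bg)
          next
        }
        m <- length(idx)
        lo <- min_gap; hi <- clen[ci] - min_gap
        if (hi - lo < m * min_gap)
          stop("cannot place ", m, " elements without overlap on contig ",
               contig_names[ci])
        pts <- NULL
        for (try in 1:100) {
          cand <- sort(sample(lo:hi, m))
          if (m == 1L || all(diff(cand) >= min_gap)) { pts <- cand; break }
        }
        if (is.null(pts))
          stop("cannot place elements without overlap on contig ",
               contig_names[ci])
        strands <- sample(c("+", "-"), m, replace = TRUE)
        pieces <- list()
        prev <- 0L
        offset <- 0L   # cumulative inserted length before current point
        for (k in seq_len(m)) {
          p <- pts[k]
          e <- idx[k]
          seq_el <- es$sequence[e]
          if (strands[k] == "-") seq_el <- .revcomp(seq_el)
          tsd <- bg[(p + 1L):(p + tsd_len)]
          pieces[[length(pieces) + 1L]] <- .int2seq(bg[(prev + 1L):p])
          pieces[[length(pieces) + 1L]] <- .int2seq(tsd)
          pieces[[length(pieces) + 1L]] <- seq_el
          pieces[[length(pieces) + 1L]] <- .int2seq(tsd)
          # element start in final contig coordinates (0-based):
          start <- p + offset + tsd_len
          bed_rows[[length(bed_rows) + 1L]] <- data.frame(
            seqname = contig_names[ci], start = start,
            end = start + nchar(seq_el), name = es$element_id[e], score = 0L,
            strand = strands[k], strain = s, subfamily = es$subfamily[e],
            class = es$class[e], stringsAsFactors = FALSE)
          # net length added per insertion: element + one extra TSD copy
          offset <- offset + nchar(seq_el) + tsd_len
          prev <- p + tsd_len   # original site consumed by left TSD copy
        }
        pieces[[length(pieces) + 1L]] <- .int2seq(bg[(prev + 1L):clen[ci]])
        fasta[contig_names[ci]] <- paste(unlist(pieces), collapse = "")
      }
    }
    bed <- if (length(bed_rows)) do.call(rbind, bed_rows) else
      data.frame(seqname = character(0), start = integer(0), end = integer(0),
                 name = character(0), score = integer(0), strand = character(0),
                 strain = character(0), subfamily = character(0),
                 class = character(0), stringsAsFactors = FALSE)
    list(fasta = fasta, bed = bed, tsd_len = tsd_len)
  })
}
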