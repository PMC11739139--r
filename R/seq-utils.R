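## Internal sequence helpers. Sequences are plain character scalars over
## ACGT(N) externally; hot loops work on integer codes 1..4 (A,C,G,T).

.BASES <- c("A", "C", "G", "T")

.seq2int <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- match(seq, .BASES)  # N/gap -> NA
  m
}

.int2seq <- function(code) {
  paste(ifelse(is.na(code), "N", .BASES[code]), collapse = "")
}

.randomSeqInt <- function(n) {
  sample.int(4L, n, replace = TRUE)
}

#' Generate a random nucleotide sequence
#'
#' Uniform i.i.d. A/C/G/T sequence, used for host background and for query
#' construction in simulations.
#'
#' @param n length in bases.
#' @param seed optional integer seed (local RNG scope).
#' @return a character scalar of length-n sequence.
#' @export
randomSequence <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    return(withr_seed(seed, randomSequence(n)))
  }
  .int2seq(.randomSeqInt(n))
}

## minimal local-seed helper (avoids a withr dependency)
withr_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.revcomp <- function(seq) {
  x <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  paste(chartr("ACGTN", "TGCAN", x), collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar over A/C/G/T/N.
#' @export
reverseComplement <- function(seq) .revcomp(seq)

## ungapped identity between equal-length character scalars
.identity <- function(a, b) {
  ai <- .seq2int(a); bi <- .seq2int(b)
  stopifnot(length(ai) == length(bi))
  ok <- !is.na(ai) & !is.na(bi)
  if (!any(ok)) return(NA_real_)
  mean(ai[ok] == bi[ok])
}

#' Construct a TEQueryModel
#'
#' @param query_id identifier.
#' @param sequence character scalar over A/C/G/T.
#' @param ltr_len length of each LTR; the remainder is the internal region.
#' @return a \linkS4class{TEQueryModel}.
#' @export
newQuery <- function(query_id, sequence, ltr_len) {
  L <- nchar(sequence)
  stopifnot(L > 2 * ltr_len)
  new("TEQueryModel", query_id = query_id, sequence = sequence,
      regions = list(ltr5 = c(0, ltr_len),
                     internal = c(ltr_len, L - ltr_len),
                     ltr3 = c(L - ltr_len, L)))
}

#' Random TEQueryModel with LTR-internal-LTR structure
#'
#' Builds a synthetic subfamily reference: identical 5' and 3' LTRs with the
#' canonical \code{TG...CA} termini flanking a random internal region.
#'
#' @param query_id identifier.
#' @param ltr_len LTR length in bp.
#' @param internal_len internal (gag/pol) region length in bp.
#' @param seed integer seed.
#' @return a \linkS4class{TEQueryModel}.
#' @export
randomQuery <- function(query_id, ltr_len = 300, internal_len = 3000, seed = 1) {
  withr_seed(seed, {
    ltr <- .randomSeqInt(ltr_len)
    # canonical terminal dinucleotides TG...CA on each LTR
    ltr[1:2] <- c(4L, 3L)                 # T G
    ltr[(ltr_len - 1):ltr_len] <- c(2L, 1L)  # C A
    int <- .randomSeqInt(internal_len)
    newQuery(query_id, .int2seq(c(ltr, int, ltr)), ltr_len)
  })
}

## region length helper
.regionLen <- function(q, region) {
  r <- queryRegions(q)[[region]]
  r[2] - r[1]
}
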