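## K2P site substitution sampling. Branch lengths are expected substitutions
## per site; kappa is the transition/transversion *rate* ratio alpha/beta.
## Per-site change probabilities use the closed-form K80 transition matrix:
##   P(transition)          = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
##   P(each transversion)   = 1/4 - 1/4 e^{-4 beta t}
## with alpha t = kappa d/(kappa+2), beta t = d/(kappa+2) so that the expected
## number of substitutions equals d.

.k2pChangeProbs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv1 <- 0.25 - 0.25 * exp(-4 * bt)  # each of the two transversion targets
  c(ts = p_ts, tv = p_tv1)
}

## evolve integer-coded sequence by expected divergence d (substitutions/site)
.evolveInt <- function(code, d, kappa) {
  if (d <= 0) return(code)
  p <- .k2pChangeProbs(d, kappa)
  n <- length(code)
  u <- runif(n)
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv"]
  out <- code
  # transition partner: A<->G (1,3), C<->T (2,4)
  out[ts] <- (code[ts] + 1L) %% 4L + 1L
  # transversions: purine (odd) -> {C,T}; pyrimidine (even) -> {A,G}
  odd <- code %% 2L == 1L
  out[tv1 & odd] <- 2L; out[tv1 & !odd] <- 1L
  out[tv2 & odd] <- 4L; out[tv2 & !odd] <- 3L
  out
}

#' Evolve a nucleotide sequence under the Kimura 2-parameter model
#'
#' Each site is mutated independently according to the closed-form K80
#' transition probabilities for a branch of expected length \code{t}
#' substitutions/site with transition/transversion rate ratio \code{kappa}.
#' The sequence length is preserved (no indels).
#'
#' @param seq character scalar over A/C/G/T.
#' @param t branch length, expected substitutions per site (>= 0).
#' @param kappa transition/transversion rate ratio (> 0, default 2).
#' @param seed optional integer seed for a deterministic draw.
#' @return the evolved sequence (character scalar, same length).
#' @examples
#' s <- randomSequence(100, seed = 1)
#' identical(evolveSequence(s, 0, 2), s)  # zero branch length
#' @export
evolveSequence <- function(seq, t, kappa = 2, seed = NULL) {
  if (t < 0) stop("branch length t must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  if (grepl("[^ACGT]", seq)) stop("sequence must contain only A/C/G/T")
  if (!is.null(seed)) return(withr_seed(seed, evolveSequence(seq, t, kappa)))
  .int2seq(.evolveInt(.seq2int(seq), t, kappa))
}
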