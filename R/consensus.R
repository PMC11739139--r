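## Strain-specific consensus building from quality-filtered base counts,
## with the depth/breadth QC gate that guards against reference-biased
## consensus sequences.

#' Filter raw site records by mapping and base quality into a pileup
#'
#' Counts bases per site from read-level records, keeping only records with
#' \code{mapq >= min_mapq} and \code{baseq >= min_baseq}.
#'
#' @param records data.frame with columns \code{pos} (1-based query
#'   position), \code{base} (A/C/G/T), \code{mapq}, \code{baseq}.
#' @param region \code{c(start, end)} 0-based half-open query interval the
#'   pileup covers.
#' @param query_id query identifier (default "query").
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_baseq minimum base quality (default 20).
#' @return a \linkS4class{PileupCounts}.
#' @export
filterSites <- function(records, region, query_id = "query",
                        min_mapq = 20, min_baseq = 20) {
  stopifnot(all(c("pos", "base", "mapq", "baseq") %in% names(records)))
  keep <- records$mapq >= min_mapq & records$baseq >= min_baseq
  rec <- records[keep, , drop = FALSE]
  n <- region[2] - region[1]
  counts <- matrix(0L, nrow = n, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(rec)) {
    row <- rec$pos - region[1]          # 1-based row index into counts
    ok <- row >= 1 & row <= n & rec$base %in% c("A", "C", "G", "T")
    rec <- rec[ok, , drop = FALSE]; row <- row[ok]
    for (i in seq_len(nrow(rec)))
      counts[row[i], rec$base[i]] <- counts[row[i], rec$base[i]] + 1L
  }
  new("PileupCounts", query_id = query_id, counts = counts, region = region)
}

#' Majority-rule consensus from a pileup
#'
#' Per site, the most frequent base is emitted when it is unique and the
#' site depth is at least \code{min_depth}; ties and under-covered sites
#' emit 'N' (missingness is made explicit rather than falling back to the
#' reference base, to avoid reference bias).  Only substitutions are
#' considered; no indels are ever emitted.
#'
#' @param pileup a \linkS4class{PileupCounts}.
#' @param min_depth minimum site depth to call a base (default 1).
#' @return consensus sequence (character scalar over A/C/G/T/N).
#' @export
majorityConsensus <- function(pileup, min_depth = 1) {
  stopifnot(is(pileup, "PileupCounts"))
  cm <- pileup@counts
  dep <- rowSums(cm)
  mx <- apply(cm, 1, max)
  n_at_max <- rowSums(cm == mx)
  call <- max.col(cm, ties.method = "first")
  code <- ifelse(dep >= min_depth & mx > 0 & n_at_max == 1L, call, NA_integer_)
  .int2seq(code)
}

#' Depth/breadth quality gate for strain-specific consensus sequences
#'
#' A strain passes when its normalized internal-region copy number strictly
#' exceeds \code{depth_min} (default 0.75) and its internal-region breadth
#' strictly exceeds \code{breadth_min} (default 0.9).  Strains failing the
#' gate are excluded from consensus-based analyses because their consensus
#' would be biased towards the query sequence.
#'
#' @param cn_internal normalized internal copy number (>= 0).
#' @param breadth internal-region breadth in [0, 1].
#' @param depth_min,breadth_min thresholds (defaults 0.75, 0.9).
#' @return logical (vectorized).
#' @examples
#' qcStrain(0.80, 0.95)  # TRUE
#' qcStrain(0.70, 0.95)  # FALSE
#' @export
qcStrain <- function(cn_internal, breadth, depth_min = 0.75,
                     breadth_min = 0.9) {
  if (any(cn_internal < 0) || any(breadth < 0))
    stop("inputs must be non-negative")
  cn_internal > depth_min & breadth > breadth_min
}

#' Build a strain consensus with QC from read evidence
#'
#' Wrapper combining \code{\link{majorityConsensus}} with the
#' \code{\link{qcStrain}} gate.
#'
#' @param pileup a \linkS4class{PileupCounts}.
#' @param cn_internal,breadth QC inputs (see \code{\link{qcStrain}}).
#' @param strain_id strain identifier.
#' @param min_depth consensus minimum site depth (default 1).
#' @param depth_min,breadth_min QC thresholds.
#' @return list with \code{strain_id}, \code{sequence}, \code{qc_pass},
#'   \code{cn_internal}, \code{breadth}.
#' @export
strainConsensus <- function(pileup, cn_internal, breadth,
                            strain_id = "strain", min_depth = 1,
                            depth_min = 0.75, breadth_min = 0.9) {
  list(strain_id = strain_id,
       sequence = majorityConsensus(pileup, min_depth = min_depth),
       qc_pass = qcStrain(cn_internal, breadth, depth_min, breadth_min),
       cn_internal = cn_internal, breadth = breadth)
}

#' Fraction of strains whose elements form within-strain monophyletic groups
#'
#' Concerted-evolution check validating the consensus-as-ancestor-proxy
#' assumption: over strains contributing at least two elements to the tree,
#' the fraction whose own elements form a monophyletic group.
#'
#' @param tree a \code{phylo} whose tips are elements.
#' @param strain_of named character vector mapping tip label to strain.
#' @return fraction in [0, 1].
#' @export
concertedEvolutionCheck <- function(tree, strain_of) {
  missing_tips <- setdiff(tree$tip.label, names(strain_of))
  if (length(missing_tips))
    stop("tips without strain labels: ", paste(missing_tips, collapse = ", "))
  strains <- strain_of[tree$tip.label]
  multi <- names(which(table(strains) >= 2))
  if (!length(multi))
    stop(structure(class = c("retroHTT_undefined", "error", "condition"),
                   list(message = paste("concerted-evolution check undefined:",
                                        "no strain has >= 2 elements"),
                        call = sys.call(-1))))
  mono <- vapply(multi, function(s) {
    tips <- tree$tip.label[strains == s]
    if (length(tips) == length(tree$tip.label)) TRUE
    else ape::is.monophyletic(tree, tips)
  }, logical(1))
  mean(mono)
}
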