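## Element annotation from homology hit tables: parsing, defragmentation
## into element-level records, and structural classification into
## full-length elements (FLE), truncated elements and solo LTRs.

.HIT_COLS <- c("score", "pct_div", "target_seq", "t_start", "t_end",
               "strand", "query_id", "q_start", "q_end")

#' Parse a whitespace-delimited homology hit table
#'
#' Reads a RepeatMasker-out-style whitespace-delimited table with columns
#' score, pct_div, target_seq, t_start, t_end, strand, query_id, q_start,
#' q_end.  Coordinates in the file are 1-based inclusive and are converted to
#' 0-based half-open; header lines (lines whose first field is not numeric)
#' are skipped; minus-strand rows with reversed query coordinates are
#' normalized to the plus-strand query frame.  Malformed rows raise an error
#' naming the line.
#'
#' @param path path to the table, or a character vector of lines.
#' @return data.frame of hits (0-based half-open coordinates).
#' @export
parseHits <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    if (suppressWarnings(is.na(as.numeric(f[1])))) next  # header line
    if (length(f) < 9L)
      stop("malformed hit row at line ", k, ": expected 9 fields")
    ts <- suppressWarnings(as.numeric(f[4])); te <- suppressWarnings(as.numeric(f[5]))
    qs <- suppressWarnings(as.numeric(f[8])); qe <- suppressWarnings(as.numeric(f[9]))
    pd <- suppressWarnings(as.numeric(f[2]))
    if (anyNA(c(ts, te, qs, qe, pd)))
      stop("malformed hit row at line ", k, ": non-numeric coordinate")
    if (!f[6] %in% c("+", "-"))
      stop("malformed hit row at line ", k, ": strand must be + or -")
    if (qs > qe) { tmp <- qs; qs <- qe; qe <- tmp }  # normalize query frame
    if (ts >= te)
      stop("malformed hit row at line ", k, ": target end <= start")
    if (pd < 0 || pd > 100)
      stop("malformed hit row at line ", k, ": pct_div outside [0,100]")
    out[[length(out) + 1L]] <- data.frame(
      score = as.numeric(f[1]), pct_div = pd, target_seq = f[3],
      t_start = ts - 1, t_end = te, strand = f[6], query_id = f[7],
      q_start = qs - 1, q_end = qe, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 9)), .HIT_COLS)
}

#' Write a hit table to a whitespace-delimited file
#'
#' Inverse of \code{\link{parseHits}}: writes 1-based inclusive coordinates
#' with a header line, round-trippable through \code{parseHits}.
#'
#' @param hits data.frame of hits (0-based half-open).
#' @param path output path.
#' @export
writeHitTable <- function(hits, path) {
  h <- hits
  h$t_start <- h$t_start + 1
  h$q_start <- h$q_start + 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.HIT_COLS, collapse = "\t"), con)
  if (nrow(h))
    write.table(h[, .HIT_COLS], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## query-collinearity check for two ordered-by-target hits on one strand:
## plus strand: query advances with target; minus: query retreats
.collinear <- function(prev, cur) {
  if (prev$strand == "+") cur$q_start >= prev$q_end
  else cur$q_end <= prev$q_start
}

#' Merge fragmented hits into element-level records
#'
#' Hits on the same target sequence, strand and query whose target gap is at
#' most \code{max_gap} and whose query intervals are collinear
#' (non-overlapping and correctly ordered for the strand) are chained into
#' one merged element.  The merged query coverage is the union of member
#' query intervals.
#'
#' @param hits data.frame from \code{\link{parseHits}} /
#'   \code{\link{emitHitTable}}.
#' @param max_gap maximum target-coordinate gap to bridge (default 250).
#' @return data.frame with one row per merged element: element_id,
#'   target_seq, start, end, strand, query_id, n_hits, pct_div (mean), and a
#'   list column \code{q_intervals} of 2-column matrices (0-based half-open
#'   query intervals).
#' @export
defragment <- function(hits, max_gap = 250) {
  if (!nrow(hits)) {
    out <- data.frame(element_id = character(0), target_seq = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), query_id = character(0),
                      n_hits = integer(0), pct_div = numeric(0),
                      stringsAsFactors = FALSE)
    out$q_intervals <- list()
    return(out)
  }
  key <- paste(hits$target_seq, hits$strand, hits$query_id, sep = "\r")
  rows <- list()
  for (k in unique(key)) {
    g <- hits[key == k, , drop = FALSE]
    g <- g[order(g$t_start), , drop = FALSE]
    cluster <- 1L
    cl <- integer(nrow(g))
    cl[1] <- cluster
    for (i in seq_len(nrow(g))[-1]) {
      prev <- g[i - 1L, ]; cur <- g[i, ]
      if (cur$t_start - prev$t_end <= max_gap && .collinear(prev, cur))
        cl[i] <- cluster
      else {
        cluster <- cluster + 1L
        cl[i] <- cluster
      }
    }
    for (c_ in unique(cl)) {
      gg <- g[cl == c_, , drop = FALSE]
      iv <- cbind(gg$q_start, gg$q_end)
      rows[[length(rows) + 1L]] <- list(
        target_seq = gg$target_seq[1], start = min(gg$t_start),
        end = max(gg$t_end), strand = gg$strand[1],
        query_id = gg$query_id[1], n_hits = nrow(gg),
        pct_div = mean(gg$pct_div), q_intervals = iv)
    }
  }
  out <- data.frame(
    element_id = sprintf("m%04d", seq_along(rows)),
    target_seq = vapply(rows, `[[`, character(1), "target_seq"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    query_id = vapply(rows, `[[`, character(1), "query_id"),
    n_hits = vapply(rows, `[[`, integer(1), "n_hits"),
    pct_div = vapply(rows, `[[`, numeric(1), "pct_div"),
    stringsAsFactors = FALSE)
  out$q_intervals <- lapply(rows, `[[`, "q_intervals")
  out
}

## fraction of each query region covered by the union of query intervals
.regionCoverage <- function(q_intervals, query) {
  regs <- queryRegions(query)
  iv <- q_intervals[order(q_intervals[, 1]), , drop = FALSE]
  vapply(regs, function(r) {
    cov <- 0
    for (i in seq_len(nrow(iv))) {
      cov <- cov + max(0, min(iv[i, 2], r[2]) - max(iv[i, 1], r[1]))
    }
    cov / (r[2] - r[1])
  }, numeric(1))
}

#' Classify a merged element into FLE / truncated / solo LTR
#'
#' Structural rule over per-region query coverage fractions: a solo LTR
#' covers at least \code{ltr_only_frac} of one LTR and less than
#' \code{max_solo_internal} of the internal region; a full-length element
#' covers at least \code{min_full_frac} of the internal region and at least
#' \code{ltr_only_frac} of both LTRs; everything else is truncated.
#'
#' @param q_intervals 2-column matrix of 0-based half-open query intervals
#'   (as in \code{\link{defragment}} output), or a named coverage vector
#'   with entries ltr5, internal, ltr3.
#' @param query the \linkS4class{TEQueryModel}.
#' @param min_full_frac minimum internal coverage for FLE (default 0.9).
#' @param ltr_only_frac minimum LTR coverage (default 0.8).
#' @param max_solo_internal maximum internal coverage for a solo LTR
#'   (default 0.05).
#' @return element class string.
#' @export
classifyElement <- function(q_intervals, query, min_full_frac = 0.9,
                            ltr_only_frac = 0.8, max_solo_internal = 0.05) {
  cov <- if (is.matrix(q_intervals)) .regionCoverage(q_intervals, query)
         else q_intervals[c("ltr5", "internal", "ltr3")]
  if ((cov["ltr5"] >= ltr_only_frac || cov["ltr3"] >= ltr_only_frac) &&
      cov["internal"] < max_solo_internal)
    return("solo_LTR")
  if (cov["internal"] >= min_full_frac && cov["ltr5"] >= ltr_only_frac &&
      cov["ltr3"] >= ltr_only_frac)
    return("FLE")
  "truncated"
}

#' Annotate and classify all elements in a hit table
#'
#' Defragments hits and applies \code{\link{classifyElement}} per merged
#' element, attaching per-region coverage fractions.
#'
#' @param hits hit data.frame (0-based half-open).
#' @param queries named list of \linkS4class{TEQueryModel} (one per
#'   query_id appearing in the hits).
#' @param max_gap defragmentation gap (default 250).
#' @param ... thresholds passed to \code{\link{classifyElement}}.
#' @return the defragment() data.frame with added columns cov_ltr5,
#'   cov_internal, cov_ltr3, class.
#' @export
annotateElements <- function(hits, queries, max_gap = 250, ...) {
  elems <- defragment(hits, max_gap = max_gap)
  n <- nrow(elems)
  covm <- matrix(NA_real_, nrow = n, ncol = 3,
                 dimnames = list(NULL, c("ltr5", "internal", "ltr3")))
  cls <- character(n)
  for (i in seq_len(n)) {
    q <- queries[[elems$query_id[i]]]
    if (is.null(q)) stop("no query model for query_id ", elems$query_id[i])
    covm[i, ] <- .regionCoverage(elems$q_intervals[[i]], q)
    cls[i] <- classifyElement(elems$q_intervals[[i]], q, ...)
  }
  elems$cov_ltr5 <- covm[, "ltr5"]
  elems$cov_internal <- covm[, "internal"]
  elems$cov_ltr3 <- covm[, "ltr3"]
  elems$class <- cls
  elems
}

#' Write annotated elements as BED6+3
#'
#' Columns: seqname, start, end, name, score (percent divergence), strand,
#' plus class, query_id and internal coverage.
#'
#' @param elements output of \code{\link{annotateElements}}.
#' @param path output path.
#' @export
writeElementsBED <- function(elements, path) {
  df <- data.frame(elements$target_seq, as.integer(elements$start),
                   as.integer(elements$end), elements$element_id,
                   round(elements$pct_div, 2), elements$strand,
                   elements$class, elements$query_id,
                   round(elements$cov_internal, 4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write annotated elements as GFF3
#'
#' @param elements output of \code{\link{annotateElements}}.
#' @param path output path.
#' @export
writeElementsGFF3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    attrs <- sprintf("ID=%s;class=%s;query=%s;cov_internal=%.4f",
                     e$element_id, e$class, e$query_id, e$cov_internal)
    writeLines(paste(e$target_seq, "retroHTT", "transposable_element",
                     as.integer(e$start) + 1L, as.integer(e$end),
                     round(e$pct_div, 2), e$strand, ".", attrs, sep = "\t"),
               con)
  }
  invisible(path)
}
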