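## Plain-text interchange: depth TSV, pileup TSV, FASTA, BED, Newick,
## run-directory manifest.

#' Write a depth profile as TSV (query_id, pos_1based, depth)
#' @param profile a \linkS4class{DepthProfile}.
#' @param path output path.
#' @export
writeDepthTSV <- function(profile, path) {
  df <- data.frame(query_id = profile@query_id,
                   pos_1based = seq_along(profile@depth),
                   depth = as.integer(round(profile@depth)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth TSV into a DepthProfile
#' @param path TSV path (columns query_id, pos_1based, depth).
#' @param baseline_depth single-copy baseline depth (required; a user-supplied
#'   scalar in real-data mode).
#' @param fold_coverage_original original fold coverage (default
#'   \code{baseline_depth}).
#' @export
readDepthTSV <- function(path, baseline_depth,
                         fold_coverage_original = baseline_depth) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  df <- df[order(df$pos_1based), ]
  new("DepthProfile", query_id = df$query_id[1],
      depth = as.numeric(df$depth), baseline_depth = baseline_depth,
      fold_coverage_original = fold_coverage_original)
}

#' Write pileup base counts as TSV (query_id, pos_1based, A, C, G, T)
#' @param pileup a \linkS4class{PileupCounts}.
#' @param path output path.
#' @export
writePileupTSV <- function(pileup, path) {
  df <- data.frame(query_id = pileup@query_id,
                   pos_1based = (pileup@region[1] + 1L):pileup@region[2],
                   pileup@counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV
#' @param path TSV path (columns query_id, pos_1based, A, C, G, T).
#' @export
readPileupTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df <- df[order(df$pos_1based), ]
  counts <- as.matrix(df[, c("A", "C", "G", "T")])
  dimnames(counts) <- list(NULL, c("A", "C", "G", "T"))
  storage.mode(counts) <- "integer"
  new("PileupCounts", query_id = df$query_id[1], counts = counts,
      region = c(df$pos_1based[1] - 1L,
                 df$pos_1based[nrow(df)]))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
writeFastaFile <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
readFastaFile <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write truth intervals as BED6
#' @param bed data.frame with seqname, start, end, name, score, strand.
#' @param path output path.
#' @export
writeBED <- function(bed, path) {
  write.table(bed[, c("seqname", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a manifest of run-directory files with checksums
#' @param dir run directory.
#' @param path manifest path (default \code{dir/manifest.tsv}).
#' @export
writeManifest <- function(dir, path = file.path(dir, "manifest.tsv")) {
  files <- setdiff(list.files(dir, recursive = TRUE),
                   basename(path))
  sums <- tools::md5sum(file.path(dir, files))
  df <- data.frame(file = files, md5 = unname(sums),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
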