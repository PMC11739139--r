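## Copy-number-from-coverage: normalized mean depth over query regions,
## breadth, down-sampling and presence/activity calls.

.resolveRegion <- function(region) {
  if (is.numeric(region)) region <- list(region)
  for (r in region) {
    if (length(r) != 2L || r[1] >= r[2])
      stop("invalid region: each interval must be c(start, end) with start < end")
  }
  region
}

#' Normalized copy number from read depth over a query region
#'
#' Mean depth over the full region (edges included) divided by the
#' single-copy baseline depth.  \code{region} may be a single
#' \code{c(start, end)} 0-based half-open interval or a list of such
#' intervals (their union is averaged, e.g. both LTRs).
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param region interval(s) on the query, 0-based half-open.
#' @return numeric copy-number estimate (>= 0).
#' @examples
#' dp <- new("DepthProfile", query_id = "q", depth = rep(30, 100),
#'           baseline_depth = 30, fold_coverage_original = 30)
#' normalizeCopyNumber(dp, c(0, 100))  # 1.0
#' @export
normalizeCopyNumber <- function(profile, region) {
  stopifnot(is(profile, "DepthProfile"))
  region <- .resolveRegion(region)
  d <- depthValues(profile)
  pos <- unlist(lapply(region, function(r) {
    if (r[1] < 0 || r[2] > length(d)) stop("region outside query bounds")
    (r[1] + 1L):r[2]
  }))
  if (!length(pos)) stop("empty region")
  mean(d[pos]) / baselineDepth(profile)
}

#' Breadth of coverage over a query region
#'
#' Fraction of region positions with depth at least \code{min_depth}.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param region interval(s) on the query, 0-based half-open.
#' @param min_depth minimum depth for a position to count as covered
#'   (default 1).
#' @return fraction in [0, 1].
#' @export
computeBreadth <- function(profile, region, min_depth = 1) {
  stopifnot(is(profile, "DepthProfile"))
  region <- .resolveRegion(region)
  d <- depthValues(profile)
  pos <- unlist(lapply(region, function(r) {
    if (r[1] < 0 || r[2] > length(d)) stop("region outside query bounds")
    (r[1] + 1L):r[2]
  }))
  if (!length(pos)) stop("empty region")
  mean(d[pos] >= min_depth)
}

#' Down-sample a depth profile to a coverage cap
#'
#' If the original fold coverage exceeds \code{cap}, per-base depths are
#' thinned binomially with probability \code{cap / fold_coverage_original}
#' (emulating read-level down-sampling) and the baseline is rescaled
#' accordingly; otherwise the profile is returned unchanged.  Deterministic
#' given \code{seed}.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param cap coverage cap (default 100).
#' @param seed integer seed.
#' @return a \linkS4class{DepthProfile}.
#' @export
downsampleDepth <- function(profile, cap = 100, seed = 1) {
  stopifnot(is(profile, "DepthProfile"))
  if (cap <= 0) stop("cap must be positive")
  f <- profile@fold_coverage_original
  if (f <= cap) return(profile)
  p <- cap / f
  withr_seed(seed, {
    new("DepthProfile", query_id = profile@query_id,
        depth = as.numeric(rbinom(length(profile@depth),
                                  as.integer(round(profile@depth)), p)),
        baseline_depth = profile@baseline_depth * p,
        fold_coverage_original = cap)
  })
}

#' Call subfamily presence from LTR and internal copy number
#'
#' Presence of the LTR portion is called when the LTR copy-number estimate
#' strictly exceeds \code{ltr_threshold} (default 1) and presence of the
#' internal region when its estimate strictly exceeds \code{int_threshold}
#' (default 0.5).
#'
#' @param cn_ltr,cn_internal copy-number estimates (>= 0), vectorized.
#' @param ltr_threshold,int_threshold presence thresholds.
#' @return data.frame with logical columns \code{presence_ltr},
#'   \code{presence_internal}.
#' @examples
#' callPresence(1.2, 0.3)  # LTR present, internal absent
#' @export
callPresence <- function(cn_ltr, cn_internal, ltr_threshold = 1,
                         int_threshold = 0.5) {
  if (any(cn_ltr < 0) || any(cn_internal < 0))
    stop("copy numbers must be non-negative")
  data.frame(presence_ltr = cn_ltr > ltr_threshold,
             presence_internal = cn_internal > int_threshold)
}

#' Interpret subfamily activity from presence calls and FLE count
#'
#' Internal-region presence or at least one full-length element is evidence
#' of relatively recent activity; LTR-only presence is compatible with either
#' recent or past activity; otherwise there is no evidence of the subfamily.
#'
#' @param presence_ltr,presence_internal logical presence calls.
#' @param n_fle number of full-length elements (>= 0).
#' @return one of \code{"recent_activity"}, \code{"past_or_recent"},
#'   \code{"no_evidence"} (vectorized).
#' @export
interpretActivity <- function(presence_ltr, presence_internal, n_fle = 0) {
  if (any(n_fle < 0)) stop("n_fle must be non-negative")
  out <- rep("no_evidence", length(presence_ltr))
  out[presence_ltr] <- "past_or_recent"
  out[presence_internal | n_fle > 0] <- "recent_activity"
  out
}

#' Copy-number estimate row for one strain and query
#'
#' Convenience wrapper computing LTR copy number (over the 5' LTR interval,
#' onto which both-LTR depth is collapsed), internal copy number, internal
#' breadth and presence calls.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param query the matching \linkS4class{TEQueryModel}.
#' @param strain_id strain identifier to record.
#' @param ltr_threshold,int_threshold presence thresholds (defaults 1, 0.5).
#' @param min_depth breadth minimum depth (default 1).
#' @return one-row data.frame: strain, query_id, cn_ltr, cn_internal,
#'   breadth_internal, presence_ltr, presence_internal.
#' @export
copyNumberEstimate <- function(profile, query, strain_id = "strain",
                               ltr_threshold = 1, int_threshold = 0.5,
                               min_depth = 1) {
  regs <- queryRegions(query)
  cn_ltr <- normalizeCopyNumber(profile, regs$ltr5)
  cn_int <- normalizeCopyNumber(profile, regs$internal)
  br <- computeBreadth(profile, regs$internal, min_depth = min_depth)
  pres <- callPresence(cn_ltr, cn_int, ltr_threshold, int_threshold)
  data.frame(strain = strain_id, query_id = queryId(query),
             cn_ltr = cn_ltr, cn_internal = cn_int, breadth_internal = br,
             presence_ltr = pres$presence_ltr,
             presence_internal = pres$presence_internal,
             stringsAsFactors = FALSE)
}
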