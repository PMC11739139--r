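# Hit parsing, defragmentation, structural classification, de novo LTR-pair
# detection and the divergent-FLE rescue path.

test_that("hit tables round-trip through text and reject malformed rows", {
  expect_equal(nrow(parseHits(character(0))), 0)
  q <- tinyQuery()
  set <- simulateElementSet(10, list(TyT = q), seed = 51)
  hits <- emitHitTable(set$run, set$elements, list(TyT = q), seed = 2)
  tf <- tempfile(fileext = ".tsv")
  writeHitTable(hits, tf)
  back <- parseHits(tf)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$t_start, hits$t_start)
  expect_equal(back$q_end, hits$q_end)
  expect_identical(back$strand, hits$strand)
  expect_error(parseHits("100 1.0 chr1 500 400 + q 1 100"), "end <= start")
  expect_error(parseHits("100 1.0 chr1 x 400 + q 1 100"), "non-numeric")
})

test_that("collinear fragments merge; opposite strands never do", {
  mk <- function(ts, te, strand, qs, qe)
    data.frame(score = 100, pct_div = 1, target_seq = "c1", t_start = ts,
               t_end = te, strand = strand, query_id = "q", q_start = qs,
               q_end = qe, stringsAsFactors = FALSE)
  two <- rbind(mk(1000, 1400, "+", 0, 400), mk(1450, 1900, "+", 450, 900))
  m <- defragment(two, max_gap = 200)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1000); expect_equal(m$end, 1900)
  expect_equal(m$n_hits, 2)
  # gap too large -> two elements
  expect_equal(nrow(defragment(two, max_gap = 20)), 2)
  # opposite strands adjacent -> never merged
  opp <- rbind(mk(1000, 1400, "+", 0, 400), mk(1450, 1900, "-", 450, 900))
  expect_equal(nrow(defragment(opp, max_gap = 200)), 2)
  # non-collinear query intervals -> not merged
  bad <- rbind(mk(1000, 1400, "+", 0, 400), mk(1450, 1900, "+", 100, 500))
  expect_equal(nrow(defragment(bad, max_gap = 200)), 2)
  # minus strand: query runs backwards along the target
  minus <- rbind(mk(1000, 1400, "-", 500, 900), mk(1450, 1900, "-", 0, 450))
  expect_equal(nrow(defragment(minus, max_gap = 200)), 1)
})

test_that("fully fragmented simulator output still yields one element per copy", {
  q <- tinyQuery()
  set <- simulateElementSet(30, list(TyT = q), seed = 52)
  hits <- emitHitTable(set$run, set$elements, list(TyT = q), frag_prob = 1,
                       seed = 3)
  # every element long enough to split yields two rows
  n_split <- sum(set$elements$q_end - set$elements$q_start > 400)
  expect_equal(nrow(hits), 30 + n_split)
  m <- defragment(hits, max_gap = 250)
  expect_equal(nrow(m), 30)
})

test_that("classification rule separates the three structural classes", {
  q <- tinyQuery()
  cov_fle <- c(ltr5 = 1.0, internal = 0.98, ltr3 = 1.0)
  cov_solo <- c(ltr5 = 0.95, internal = 0.0, ltr3 = 0.0)
  cov_trunc <- c(ltr5 = 1.0, internal = 0.5, ltr3 = 0.0)
  expect_identical(classifyElement(cov_fle, q), "FLE")
  expect_identical(classifyElement(cov_solo, q), "solo_LTR")
  expect_identical(classifyElement(cov_trunc, q), "truncated")
})

test_that("annotated elements recover true classes from fragmented hits", {
  # realistic region sizes: fragmentation gaps (<= 120 bp) must stay small
  # against the internal region for coverage-based classification
  q <- randomQuery("TyT", ltr_len = 200, internal_len = 2000, seed = 53)
  set <- simulateElementSet(60, list(TyT = q), seed = 53,
                            divergence_range = c(0, 0.15))
  hits <- emitHitTable(set$run, set$elements, list(TyT = q), frag_prob = 0.5,
                       seed = 4)
  ann <- annotateElements(hits, list(TyT = q))
  expect_equal(nrow(ann), 60)
  # class counts conservation
  expect_equal(sum(ann$class == "FLE") + sum(ann$class == "truncated") +
                 sum(ann$class == "solo_LTR"), nrow(ann))
  # match each truth element to the annotation at its locus
  ok <- 0
  for (i in seq_len(nrow(set$run$bed))) {
    b <- set$run$bed[i, ]
    j <- which(ann$target_seq == b$seqname & ann$start < b$end &
                 ann$end > b$start)
    truth <- set$elements$class[set$elements$element_id == b$name]
    if (length(j) == 1 && identical(ann$class[j], truth)) ok <- ok + 1
  }
  expect_gte(ok / nrow(set$run$bed), 0.95)
})

test_that("planted LTR pairs are found at their exact coordinates", {
  set.seed(99)
  ltr <- paste0("TG", randomSequence(296), "CA")
  tsd <- randomSequence(5)
  genome <- paste0(randomSequence(2000), tsd, ltr, randomSequence(4400), ltr,
                   tsd, randomSequence(2000))
  cands <- detectLTRPairs(c(chr = genome))
  expect_equal(nrow(cands), 1)
  expect_equal(cands$left_start, 2006)
  expect_equal(cands$left_end, 2305)                      # 300-bp repeat
  expect_equal(cands$right_start - cands$left_start, 300 + 4400)
  expect_true(cands$tsd); expect_true(cands$motif)
  expect_gte(cands$identity, 0.999)
})

test_that("distance and identity bounds are enforced", {
  set.seed(100)
  ltr <- paste0("TG", randomSequence(296), "CA")
  tsd <- randomSequence(5)
  # 1 kb apart: below min_dist -> no candidate
  close_genome <- paste0(randomSequence(1500), tsd, ltr,
                         randomSequence(700), ltr, tsd,
                         randomSequence(1500))
  expect_equal(nrow(detectLTRPairs(c(chr = close_genome))), 0)
  # ~75% identity -> rejected at min_identity = 0.80
  ltr2 <- evolveSequence(ltr, 0.32, 2)  # expected identity ~0.75
  div_genome <- paste0(randomSequence(1500), tsd, ltr, randomSequence(4000),
                       ltr2, tsd, randomSequence(1500))
  cands <- detectLTRPairs(c(chr = div_genome), motif_required = FALSE,
                          tsd_required = FALSE)
  expect_true(nrow(cands) == 0 || all(cands$identity >= 0.80))
})

test_that("pure random megabase sequence yields no candidates", {
  g <- randomSequence(1e6, seed = 1234)
  expect_equal(nrow(detectLTRPairs(c(chr = g))), 0)
})

test_that("dispersed divergent elements are rescued as FLEs", {
  # a diverged subfamily: 5 near-identical copies across 2 contigs, each a
  # proper LTR-structured element, classified 'truncated' by the homology
  # step because the query is too far away
  q <- tinyQuery("TyQ", ltr = 300, internal = 3000, seed = 61)
  divergent <- evolveSequence(querySequence(q), 0.25, 2, seed = 62)
  # restore tg...ca termini on both LTRs so structure detection applies
  fix <- function(s) {
    substr(s, 1, 2) <- "TG"; substr(s, 299, 300) <- "CA"
    substr(s, 3301, 3302) <- "TG"; substr(s, 3599, 3600) <- "CA"
    s
  }
  divergent <- fix(divergent)
  # recent insertions: each copy's two LTRs are identical at insertion
  sameLTRs <- function(s) {
    substr(s, 3301, 3600) <- substr(s, 1, 300)
    s
  }
  el <- do.call(rbind, lapply(1:5, function(i) data.frame(
    element_id = sprintf("d%d", i), strain = "s1", subfamily = "TyQ",
    class = "FLE", q_start = 0L, q_end = 3600L,
    sequence = evolveSequence(divergent, 0.01, 2, seed = 70 + i),
    ancestry = "vertical", origin = "t", breakpoints = "", parents = "",
    stringsAsFactors = FALSE)))
  el$sequence <- vapply(el$sequence, function(s) sameLTRs(fix(s)),
                        character(1))
  run <- emitGenomes(el, background_length = 60000, seed = 63, n_contigs = 2)
  # homology annotation saw them as truncated
  ann <- data.frame(element_id = sprintf("m%d", 1:5),
                    target_seq = run$bed$seqname,
                    start = run$bed$start, end = run$bed$end,
                    strand = run$bed$strand, query_id = "TyQ",
                    n_hits = 1L, pct_div = 25,
                    cov_ltr5 = 0.6, cov_internal = 0.6, cov_ltr3 = 0.2,
                    class = "truncated", stringsAsFactors = FALSE)
  cands <- detectLTRPairs(run$fasta)
  expect_gte(nrow(cands), 5)
  rescued <- rescueDivergentFLE(ann, cands, run$fasta,
                                min_mutual_identity = 0.9, min_count = 3)
  expect_true(all(rescued$class == "FLE"))
  expect_true(all(rescued$rescued))
  # a single divergent copy is never promoted (count guard)
  solo <- rescueDivergentFLE(ann[1, ], cands, run$fasta, min_count = 3)
  expect_identical(solo$class, "truncated")
  # elements without candidate overlap stay unchanged
  far <- ann
  far$start <- far$start + 50000; far$end <- far$end + 50000
  unchanged <- rescueDivergentFLE(far, cands, run$fasta, min_count = 3)
  expect_true(all(unchanged$class == "truncated"))
})
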