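# Forward simulator: sequence evolution, host trees, family histories,
# genome emission, read evidence and hit tables.

test_that("zero branch length leaves sequences untouched", {
  s <- randomSequence(300, seed = 1)
  expect_identical(evolveSequence(s, 0, 2, seed = 5), s)
  expect_error(evolveSequence("ACGN", 0.1, 2), "A/C/G/T")
  expect_error(evolveSequence("ACGT", -1, 2), "non-negative")
})

test_that("realized divergence matches the K2P expectation", {
  s <- randomSequence(10000, seed = 2)
  e <- evolveSequence(s, 0.10, 2, seed = 3)
  d <- k2p(s, e)$d
  # Monte-Carlo SD of the distance estimate at d=0.1 over 10 kb is ~0.0035
  expect_lt(abs(d - 0.10), 3 * 0.0035)
})

test_that("transition:transversion counts follow the K2P rate mix", {
  s <- randomSequence(20000, seed = 4)
  e <- evolveSequence(s, 0.08, 2, seed = 5)
  si <- strsplit(s, "")[[1]]; ei <- strsplit(e, "")[[1]]
  diff <- si != ei
  ts <- sum(diff & ((si %in% c("A", "G") & ei %in% c("A", "G")) |
                    (si %in% c("C", "T") & ei %in% c("C", "T"))))
  tv <- sum(diff) - ts
  p <- retroHTT:::.k2pChangeProbs(0.08, 2)
  expected_ratio <- p["ts"] / (2 * p["tv"])
  expect_lt(abs(ts / tv - expected_ratio), 0.25)
})

test_that("host trees are deterministic under a fixed seed and vary across seeds", {
  t1 <- simulateHostTree(8, 0.1, seed = 42)
  t2 <- simulateHostTree(8, 0.1, seed = 42)
  t3 <- simulateHostTree(8, 0.1, seed = 43)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  # smallest tree
  t0 <- simulateHostTree(2, 0.1, seed = 1)
  expect_equal(length(t0$tip.label), 2)
  expect_true(all(t0$edge.length > 0))
  expect_error(simulateHostTree(1, 0.1), "at least 2")
})

test_that("lineage-structured trees keep lineages monophyletic", {
  tr <- simulateHostTree(9, 0.1, seed = 7, n_lineages = 3)
  lin <- hostLineages(tr)
  expect_equal(length(lin), 9)
  for (L in unique(lin)) {
    tips <- names(lin)[lin == L]
    if (length(tips) > 1)
      expect_true(ape::is.monophyletic(tr, tips))
  }
})

test_that("null process: tips carry the root inventory evolved by substitution only", {
  q <- tinyQuery()
  tr <- ape::read.tree(text = "((s01:0.05,s02:0.05)n2:0.05,s03:0.1)n1;")
  sim <- simulateFamilyHistory(tr, list(
    seed = 3, transposition_rate = 0, solo_ltr_rate = 0,
    truncation_rate = 0, loss_rate = 0), list(q), root_copies = 2)
  el <- simElements(sim)
  expect_equal(nrow(el), 6)                      # 2 copies x 3 tips
  expect_true(all(el$class == "FLE"))
  expect_true(all(table(el$strain) == 2))
  expect_equal(nrow(simEvents(sim)), 0)
  # same element id in sister strains descends from one root copy:
  # distance consistent with path length 0.1 (not more than saturation)
  pair <- el[el$element_id == el$element_id[1], ]
  d <- k2p(pair$sequence[1], pair$sequence[2])$d
  expect_lt(abs(d - 0.1), 0.08)
})

test_that("family simulation is deterministic given the seed", {
  q <- tinyQuery()
  tr <- simulateHostTree(4, 0.08, seed = 5)
  s1 <- simulateFamilyHistory(tr, list(seed = 9), list(q))
  s2 <- simulateFamilyHistory(tr, list(seed = 9), list(q))
  expect_identical(simElements(s1), simElements(s2))
  expect_identical(simEvents(s1), simEvents(s2))
})

test_that("htt events reference existing branches and move donor state", {
  qA <- tinyQuery("TyA", seed = 1)
  qB <- tinyQuery("TyB", seed = 2)
  tr <- ape::read.tree(text =
    "((s01:0.06,s02:0.06)n2:0.06,(s03:0.06,s04:0.06)n3:0.06)n1;")
  expect_error(simulateFamilyHistory(tr, list(
    htt_events = list(list(donor = "zz", recipient = "s01", time = 0.5))),
    list(qA)), "nonexistent")
  sim <- simulateFamilyHistory(tr, list(
    seed = 11, transposition_rate = 0, solo_ltr_rate = 0,
    truncation_rate = 0, loss_rate = 0,
    extinction_events = list(list(branch = "n3", time = 0.05,
                                  subfamily = "TyB")),
    htt_events = list(list(donor = "n2", recipient = "s04", time = 0.5,
                           subfamily = "TyB"))),
    list(qA, qB), root_copies = 1)
  el <- simElements(sim)
  # s03 lost TyB; s04 regained it horizontally
  expect_equal(sum(el$strain == "s03" & el$subfamily == "TyB"), 0)
  htt_el <- el[el$strain == "s04" & el$subfamily == "TyB", ]
  expect_equal(nrow(htt_el), 1)
  expect_identical(htt_el$ancestry, "htt")
  # transferred element is closer (K2P) to donor-side TyB than any
  # vertically inherited element in its own clade is
  donor_b <- el[el$strain %in% c("s01", "s02") & el$subfamily == "TyB", ]
  d_cross <- min(vapply(donor_b$sequence, function(x)
    k2p(htt_el$sequence, x)$d, numeric(1)))
  own_a <- el[el$strain == "s04" & el$subfamily == "TyA", ]
  d_own <- k2p(htt_el$sequence, own_a$sequence[1])$d
  expect_lt(d_cross, d_own)
  # and closer than the full donor-recipient host path would imply
  expect_lt(d_cross, 0.12)
})

test_that("recombination creates the exact mosaic at creation time", {
  qA <- tinyQuery("TyA", seed = 1)
  qB <- tinyQuery("TyB", seed = 2)
  tr <- ape::read.tree(text = "(s01:0.05,s02:0.05)n1;")
  b1 <- 200
  sim <- simulateFamilyHistory(tr, list(
    seed = 2, sub_rate = 0, transposition_rate = 0, solo_ltr_rate = 0,
    truncation_rate = 0, loss_rate = 0,
    recomb_events = list(list(branch = "s01", time = 0.5, parentA = "TyA",
                              parentB = "TyB", breakpoints = b1,
                              name = "chim"))),
    list(qA, qB), root_copies = 1)
  el <- simElements(sim)
  chim <- el[el$subfamily == "chim", ]
  expect_equal(nrow(chim), 1)
  expect_identical(chim$ancestry, "recombinant")
  expect_identical(chim$breakpoints, "200")
  expected <- paste0(substr(querySequence(qA), 1, b1),
                     substr(querySequence(qB), b1 + 1,
                            nchar(querySequence(qB))))
  expect_identical(chim$sequence, expected)
  # breakpoints must fall inside the internal region
  expect_error(simulateFamilyHistory(tr, list(
    recomb_events = list(list(branch = "s01", time = 0.5, parentA = "TyA",
                              parentB = "TyB", breakpoints = 10))),
    list(qA, qB)), "internal region")
})

test_that("solo-LTR formation conserves LTR counts", {
  q <- tinyQuery()
  tr <- simulateHostTree(4, 0.1, seed = 3)
  sim <- simulateFamilyHistory(tr, list(
    seed = 4, transposition_rate = 0.5, solo_ltr_rate = 0.6,
    truncation_rate = 0, loss_rate = 0), list(q), root_copies = 2)
  el <- simElements(sim)
  for (s in unique(el$strain)) {
    es <- el[el$strain == s, ]
    n_fle <- sum(es$class == "FLE")
    n_solo <- sum(es$class == "solo_LTR")
    expect_equal(trueCopyNumber(sim, s, "TyT", "ltr"), 2 * n_fle + n_solo)
    expect_equal(trueCopyNumber(sim, s, "TyT", "internal"), n_fle)
  }
})

test_that("truth alignments are gap-free and K2P-consistent with the tree", {
  q <- randomQuery("TyT", ltr_len = 100, internal_len = 5000, seed = 21)
  tr <- ape::read.tree(text = "(s01:0.05,s02:0.05)n1;")
  sim <- simulateFamilyHistory(tr, list(
    seed = 6, transposition_rate = 0, solo_ltr_rate = 0,
    truncation_rate = 0, loss_rate = 0), list(q), root_copies = 1)
  aln <- truthAlignment(sim)
  expect_equal(length(aln), 2)
  expect_equal(unique(nchar(aln)), 5000)
  expect_false(any(grepl("-", aln)))
  d <- k2p(aln[[1]], aln[[2]])$d
  # path length 0.1 over >= 5 kb: within 3 Monte-Carlo SD (~0.0047)
  expect_lt(abs(d - 0.1), 3 * 0.0047)
})

test_that("genome emission embeds elements exactly at BED intervals", {
  q <- tinyQuery()
  el <- data.frame(element_id = "e1", strain = "s1", subfamily = "TyT",
                   class = "FLE", q_start = 0L,
                   q_end = nchar(querySequence(q)),
                   sequence = querySequence(q), ancestry = "vertical",
                   origin = "t", breakpoints = "", parents = "",
                   stringsAsFactors = FALSE)
  run <- emitGenomes(el, background_length = 12000, seed = 8, n_contigs = 1)
  expect_equal(nrow(run$bed), 1)
  b <- run$bed[1, ]
  embedded <- substr(run$fasta[[b$seqname]], b$start + 1, b$end)
  expected <- if (b$strand == "-") reverseComplement(el$sequence) else
    el$sequence
  expect_identical(embedded, expected)
  # TSD flanks the insertion
  tsd_l <- substr(run$fasta[[b$seqname]], b$start - run$tsd_len + 1, b$start)
  tsd_r <- substr(run$fasta[[b$seqname]], b$end + 1, b$end + run$tsd_len)
  expect_identical(tsd_l, tsd_r)
})

test_that("many elements are placed without overlap on both strands", {
  q <- tinyQuery()
  set.seed(10)
  el <- do.call(rbind, lapply(1:20, function(i) data.frame(
    element_id = sprintf("e%02d", i), strain = "s1", subfamily = "TyT",
    class = "FLE", q_start = 0L, q_end = nchar(querySequence(q)),
    sequence = querySequence(q), ancestry = "vertical", origin = "t",
    breakpoints = "", parents = "", stringsAsFactors = FALSE)))
  run <- emitGenomes(el, background_length = 60000, seed = 9, n_contigs = 2)
  expect_equal(nrow(run$bed), 20)
  for (cn in unique(run$bed$seqname)) {
    b <- run$bed[run$bed$seqname == cn, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1)
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  expect_setequal(unique(run$bed$strand), c("+", "-"))
  # minus-strand element appears reverse complemented
  mb <- run$bed[run$bed$strand == "-", ][1, ]
  expect_identical(substr(run$fasta[[mb$seqname]], mb$start + 1, mb$end),
                   reverseComplement(querySequence(q)))
})

test_that("depth simulation recovers absence and known copy numbers", {
  q <- tinyQuery(ltr = 100, internal = 1000, seed = 12)
  z <- simulateStrainWithCopies(0, q, seed = 31, fold_coverage = 30)
  dp <- z$evidence$depth
  expect_true(all(depthValues(dp) == 0))
  expect_lt(abs(baselineDepth(dp) - 30) / 30, 0.15)
  regs <- queryRegions(q)
  cn1 <- mean(vapply(1:5, function(r) {
    one <- simulateStrainWithCopies(1, q, seed = 320 + r, fold_coverage = 30)
    normalizeCopyNumber(one$evidence$depth, regs$internal)
  }, numeric(1)))
  expect_gte(cn1, 0.85); expect_lte(cn1, 1.15)
  cn10 <- mean(vapply(1:3, function(r) {
    ten <- simulateStrainWithCopies(10, q, seed = 330 + r,
                                    fold_coverage = 30, divergence = 0)
    normalizeCopyNumber(ten$evidence$depth, regs$internal)
  }, numeric(1)))
  expect_gte(cn10, 8.5); expect_lte(cn10, 11.5)
})

test_that("hit tables fragment on demand and stay within bounds", {
  q <- tinyQuery()
  set <- simulateElementSet(10, list(TyT = q), seed = 41,
                            class_probs = c(1, 0, 0))
  h0 <- emitHitTable(set$run, set$elements, list(TyT = q), frag_prob = 0,
                     seed = 1)
  expect_equal(nrow(h0), 10)
  h1 <- emitHitTable(set$run, set$elements, list(TyT = q), frag_prob = 1,
                     seed = 1)
  expect_gte(nrow(h1), 20)
  lens <- nchar(set$run$fasta)[h1$target_seq]
  expect_true(all(h1$t_start >= 0 & h1$t_end <= lens))
  expect_true(all(h1$q_start >= 0 & h1$q_end <= nchar(querySequence(q))))
})
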