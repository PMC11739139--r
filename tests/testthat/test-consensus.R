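# Quality filtering, majority consensus, QC gate, concerted-evolution check.

test_that("quality filters keep exactly the passing records", {
  rec <- data.frame(
    pos = c(1, 1, 1, 2, 2, 2, 3, 3, 4, 4),
    base = c("A", "A", "C", "G", "G", "G", "T", "A", "C", "C"),
    mapq = c(60, 10, 60, 60, 60, 19, 60, 60, 60, 60),
    baseq = c(30, 30, 15, 30, 30, 30, 30, 30, 30, 5),
    stringsAsFactors = FALSE)
  pu <- filterSites(rec, region = c(0, 4))
  # hand tally of records with mapq>=20 and baseq>=20:
  # pos1: A(1); pos2: G(2); pos3: T+A; pos4: C(1)
  expect_equal(unname(pu@counts[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(pu@counts[2, ]), c(0, 0, 2, 0))
  expect_equal(unname(pu@counts[3, ]), c(1, 0, 0, 1))
  expect_equal(unname(pu@counts[4, ]), c(0, 1, 0, 0))
  # all below threshold -> zero depth
  none <- filterSites(rec, region = c(0, 4), min_mapq = 99)
  expect_true(all(none@counts == 0))
  # thresholds 0 -> raw tally
  raw <- filterSites(rec, region = c(0, 4), min_mapq = 0, min_baseq = 0)
  expect_equal(sum(raw@counts), 10)
})

test_that("majority consensus calls bases, ties and low depth correctly", {
  cm <- rbind(c(10, 0, 0, 0),   # A
              c(5, 5, 0, 0),    # tie -> N
              c(0, 0, 0, 0),    # no depth -> N
              c(0, 1, 0, 0))    # single C
  pu <- pileupFromCounts(cm)
  expect_identical(majorityConsensus(pu), "ANNC")
  expect_identical(majorityConsensus(pu, min_depth = 2), "ANNN")
})

test_that("QC gate applies strict depth/breadth thresholds", {
  expect_true(qcStrain(0.80, 0.95))
  expect_false(qcStrain(0.70, 0.95))
  expect_false(qcStrain(0.80, 0.85))
  expect_false(qcStrain(0.75, 0.95))   # boundary is strict
  expect_error(qcStrain(-1, 0.5), "non-negative")
})

test_that("error-free consensus equals the truth; 1% error stays above 99.9%", {
  q <- tinyQuery("TyC", ltr = 100, internal = 1000, seed = 81)
  regs <- queryRegions(q)
  truth_int <- substr(querySequence(q), regs$internal[1] + 1,
                      regs$internal[2])
  # three identical copies, error-free reads
  z0 <- simulateStrainWithCopies(3, q, seed = 82, divergence = 0, err = 0)
  cons0 <- majorityConsensus(z0$evidence$pileup)
  covered <- strsplit(cons0, "")[[1]] != "N"
  expect_true(all(covered))
  expect_identical(cons0, truth_int)
  # 1% read error at 30x
  z1 <- simulateStrainWithCopies(3, q, seed = 83, divergence = 0, err = 0.01)
  cons1 <- majorityConsensus(z1$evidence$pileup)
  ident <- mean(strsplit(cons1, "")[[1]] == strsplit(truth_int, "")[[1]])
  expect_gte(ident, 0.999)
})

test_that("true-absence strains never pass QC", {
  q <- tinyQuery("TyC", ltr = 100, internal = 1000, seed = 81)
  z <- simulateStrainWithCopies(0, q, seed = 84)
  regs <- queryRegions(q)
  cn <- normalizeCopyNumber(z$evidence$depth, regs$internal)
  br <- computeBreadth(z$evidence$depth, regs$internal)
  expect_false(qcStrain(cn, br))
})

test_that("consensus is a better ancestor proxy than single paralogs", {
  # strain with diverged paralogs: consensus should sit closer to their
  # common ancestor than the median single copy does
  q <- tinyQuery("TyC", ltr = 100, internal = 1000, seed = 85)
  regs <- queryRegions(q)
  anc_int <- substr(querySequence(q), regs$internal[1] + 1, regs$internal[2])
  wins <- 0
  for (r in 1:10) {
    z <- simulateStrainWithCopies(5, q, seed = 90 + r, divergence = 0.03,
                                  err = 0.005)
    cons <- majorityConsensus(z$evidence$pileup)
    d_cons <- k2p(cons, anc_int)$d
    d_copies <- vapply(z$elements$sequence, function(s)
      k2p(substr(s, regs$internal[1] + 1, regs$internal[2]), anc_int)$d,
      numeric(1))
    if (d_cons <= median(d_copies)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("concerted-evolution fraction matches brute-force monophyly", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,((b1:1,b2:1):1,c1:2):1);")
  so <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  expect_equal(concertedEvolutionCheck(tr, so), 1.0)
  mixed <- ape::read.tree(text = "((a1:1,b1:1):1,((a2:1,b2:1):1,c1:2):1);")
  expect_equal(concertedEvolutionCheck(mixed, so), 0.0)
  one <- ape::read.tree(text = "((a1:1,a2:1):1,c1:2);")
  expect_equal(concertedEvolutionCheck(one, so[c("a1", "a2", "c1")]), 1.0)
  # no strain with >= 2 elements: distinct signal
  expect_error(concertedEvolutionCheck(
    ape::read.tree(text = "(a1:1,(b1:1,c1:1):1);"),
    c(a1 = "A", b1 = "B", c1 = "C")), class = "retroHTT_undefined")
})
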