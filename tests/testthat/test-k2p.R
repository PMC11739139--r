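# K2P distance engine, sliding windows, breakpoint calling, partitions.

test_that("k2p matches the closed form on a constructed pair", {
  # 20 sites, 2 transitions (A->G), 1 transversion (A->C): P=0.1, Q=0.05
  a <- strrep("A", 20)
  b <- paste0("GGC", strrep("A", 17))
  r <- k2p(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_identical(r$status, "ok")
})

test_that("identical sequences give zero distance", {
  s <- randomSequence(500, seed = 3)
  r <- k2p(s, s)
  expect_equal(r$d, 0)
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)
})

test_that("k2p is symmetric and honours pairwise deletion", {
  set.seed(42)
  for (i in 1:25) {
    a <- randomSequence(200)
    b <- evolveSequence(a, runif(1, 0, 0.3), 2)
    expect_equal(k2p(a, b)$d, k2p(b, a)$d)
    # appending N columns leaves d unchanged
    aN <- paste0(a, strrep("N", 10))
    bN <- paste0(b, randomSequence(10))
    expect_equal(k2p(aN, bN)$d, k2p(a, b)$d)
  }
})

test_that("saturation and zero-site cases are signalled, not numeric", {
  a <- strrep("A", 10)
  b <- strrep("G", 10)  # P = 1 -> saturated
  r <- k2p(a, b)
  expect_identical(r$status, "saturated")
  expect_true(is.na(r$d))
  r2 <- k2p(strrep("N", 5), strrep("A", 5))
  expect_identical(r2$status, "no_sites")
  expect_true(is.na(r2$d))
  expect_error(k2p("ACGT", "ACG"), "equal length")
})

test_that("k2p agrees with an established K80 implementation", {
  set.seed(7)
  for (i in 1:10) {
    a <- randomSequence(1000)
    b <- evolveSequence(a, runif(1, 0.02, 0.25), 2)
    m <- rbind(a = strsplit(tolower(a), "")[[1]],
               b = strsplit(tolower(b), "")[[1]])
    d_ape <- ape::dist.dna(ape::as.DNAbin(m), model = "K80")
    expect_equal(k2p(a, b)$d, as.numeric(d_ape), tolerance = 1e-12)
  }
})

test_that("k2p reduces to Jukes-Cantor at the 1:2 transition:transversion mix", {
  # constructed pair: 3k sites with differences split 1:2 between
  # transitions and transversions (the proportions equal rates imply)
  n <- 3000
  a <- strrep("A", n)
  ndiff <- 300
  b_chars <- rep("A", n)
  b_chars[1:100] <- "G"             # transitions
  b_chars[101:200] <- "C"           # transversions
  b_chars[201:300] <- "T"           # transversions
  b <- paste(b_chars, collapse = "")
  p <- ndiff / n
  d_jc <- -3 / 4 * log(1 - 4 / 3 * p)
  expect_equal(k2p(a, b)$d, d_jc, tolerance = 1e-12)
})

test_that("sliding windows count and locate correctly", {
  a <- randomSequence(100, seed = 5)
  prof <- slidingWindowDivergence(a, c(p1 = a), w = 50, s = 10)
  # floor((100-50)/10)+1 = 6 windows
  expect_equal(length(prof@centers), 6)
  expect_true(all(prof@d[, "p1"] == 0))
  expect_error(slidingWindowDivergence(substr(a, 1, 30), c(p = substr(a, 1, 30)),
                                       w = 50),
               "shorter")
})

test_that("a constructed chimera separates its parents window by window", {
  set.seed(9)
  A <- randomSequence(1000)
  B <- evolveSequence(A, 0.10, 2)
  chim <- paste0(substr(A, 1, 500), substr(B, 501, 1000))
  prof <- slidingWindowDivergence(chim, c(A = A, B = B), w = 50, s = 10)
  left <- prof@centers < 450
  right <- prof@centers > 550
  expect_true(all(prof@d[left, "A"] <= prof@d[left, "B"]))
  expect_true(all(prof@d[right, "A"] >= prof@d[right, "B"]))
})

test_that("breakpoint inference recovers planted breakpoints", {
  set.seed(31)
  hits <- 0; n_rep <- 20
  for (i in 1:n_rep) {
    A <- randomSequence(2000)
    B <- evolveSequence(A, runif(1, 0.05, 0.15), 2)
    bp <- sample(600:1400, 1)
    chim <- paste0(substr(A, 1, bp), substr(B, bp + 1, 2000))
    prof <- slidingWindowDivergence(chim, c(A = A, B = B))
    call <- inferBreakpoints(prof)
    if (length(call$breakpoints) == 1 &&
        abs(call$breakpoints - bp) <= 50 &&
        identical(call$segments$parent, c("A", "B")))
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("no breakpoints are called on pure candidates", {
  set.seed(17)
  for (i in 1:20) {
    A <- randomSequence(2000)
    B <- evolveSequence(A, runif(1, 0.05, 0.15), 2)
    cand <- evolveSequence(A, 0.02, 2)
    call <- inferBreakpoints(slidingWindowDivergence(cand, c(A = A, B = B)))
    expect_length(call$breakpoints, 0)
  }
})

test_that("two-breakpoint chimeras yield alternating segment parents", {
  set.seed(23)
  A <- randomSequence(3000)
  B <- evolveSequence(A, 0.12, 2)
  b1 <- 900; b2 <- 2100
  chim <- paste0(substr(A, 1, b1), substr(B, b1 + 1, b2),
                 substr(A, b2 + 1, 3000))
  call <- inferBreakpoints(slidingWindowDivergence(chim, c(A = A, B = B)))
  expect_length(call$breakpoints, 2)
  expect_true(abs(call$breakpoints[1] - b1) <= 50)
  expect_true(abs(call$breakpoints[2] - b2) <= 50)
  expect_identical(call$segments$parent, c("A", "B", "A"))
})

test_that("partitionAlignment slices exactly and conserves columns", {
  msa <- c(x = randomSequence(120, seed = 2), y = randomSequence(120, seed = 3))
  # full-range single partition: identity
  p1 <- partitionAlignment(msa, list(all = c(1, 120)))
  expect_identical(unname(p1$all), unname(msa))
  # two partitions: widths sum to alignment length, concatenation restores
  p2 <- partitionAlignment(msa, list(l = c(1, 47), r = c(48, 120)))
  expect_identical(paste0(p2$l["x"], p2$r["x"]), unname(msa["x"]))
  expect_equal(unname(nchar(p2$l[1]) + nchar(p2$r[1])), 120)
  expect_error(partitionAlignment(msa, list(a = c(1, 60), b = c(50, 120))),
               "overlap")
  expect_error(partitionAlignment(msa, list(a = c(0, 60))), "within")
})

test_that("alignment columns map back to ungapped positions", {
  expect_equal(alignmentColumnToSeqPos("AC-GT", 4), 3)
  expect_true(is.na(alignmentColumnToSeqPos("AC-GT", 3)))
})
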