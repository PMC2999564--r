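test_that("lambda solves the Karlin-Altschul equation", {
  # +1/-1 uniform: sum p_i p_j exp(lambda s) = 1 reduces to
  # (1/4) x + (3/4) / x = 1 with x = exp(lambda), so x = 3, lambda = ln 3
  ka <- solveLambda(scoringParams(1, -1))
  expect_equal(ka@lambda, log(3), tolerance = 1e-9)

  # +1/-2 uniform: independent bisection of the scalar equation
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 0.5; hi <- 3
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  ka2 <- solveLambda(scoringParams(1, -2))
  expect_equal(ka2@lambda, (lo + hi) / 2, tolerance = 1e-9)

  # scaling all scores by 2 halves lambda
  ka4 <- solveLambda(scoringParams(2, -4))
  expect_equal(ka4@lambda, ka2@lambda / 2, tolerance = 1e-9)

  # frozen reference values for the default scoring (standard ungapped
  # BLASTN constants for +1/-2, uniform composition)
  expect_equal(ka2@lambda, 1.33, tolerance = 0.005)
  expect_equal(ka2@K, 0.621, tolerance = 0.005)
  expect_equal(ka2@H, 1.12, tolerance = 0.005)

  # non-negative expected score is rejected
  expect_error(solveLambda(scoringParams(3, -1)), "negative")
})

test_that("E-values follow K m n exp(-lambda s)", {
  ka <- solveLambda(scoringParams(1, -2))
  e1 <- evalueKA(30, 100, 1000, ka)
  expect_equal(e1, ka@K * 100 * 1000 * exp(-ka@lambda * 30))
  # linear in n, monotone decreasing in score
  expect_equal(evalueKA(30, 100, 2000, ka), 2 * e1)
  expect_true(all(diff(evalueKA(10:40, 100, 1000, ka)) < 0))
  expect_lt(evalueKA(1000, 100, 1000, ka), 1e-300)
})

test_that("self- and embedded alignments are recovered exactly", {
  set.seed(21)
  s <- rnd_seq(60)
  h <- localAlign(setNames(s, "q"), setNames(s, "s"), minScore = 10)
  self <- h[h$strand == "+", ][1, ]
  expect_identical(self$aligned_cols, 60L)
  expect_identical(self$identities, 60L)
  expect_identical(self$score, 60L)

  # 30-base sequence embedded verbatim in a 200-base background
  bg <- rnd_seq(200)
  ins <- substr(bg, 71, 100)
  h2 <- localAlign(setNames(ins, "q"), setNames(bg, "s"), minScore = 20)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$q_start, 0L)
  expect_identical(h2$q_end, 30L)
  expect_identical(h2$s_start, 70L)
  expect_identical(h2$s_end, 100L)
  expect_identical(h2$identities, 30L)
})

test_that("minus-strand hits mirror plus-strand hits", {
  set.seed(22)
  a <- rnd_seq(80); b <- rnd_seq(150)
  substr(b, 40, 40 + 39) <- substr(a, 20, 59)  # share a 40-mer
  hf <- localAlign(setNames(a, "q"), setNames(b, "s"), minScore = 20)
  hr <- localAlign(setNames(a, "q"), setNames(revComp(b), "s"),
                   minScore = 20)
  expect_identical(hf$score, hr$score)
  expect_identical(hf$identities, hr$identities)
  expect_setequal(c(hf$strand, hr$strand), c("+", "-"))
})

test_that("seeded aligner equals independent DP oracles on short pairs", {
  # convention triangulation on a handful of pairs: the scalar-loop DP and
  # the Biostrings local aligner agree with the implementation
  set.seed(23)
  for (k in 1:10) {
    a <- rnd_seq(sample(10:35, 1)); b <- rnd_seq(sample(10:35, 1))
    ours <- localAlign(setNames(a, "q"), setNames(b, "s"),
                       minScore = 5L, wordSize = 3L)
    mine <- if (nrow(ours)) max(ours$score) else 0L
    oracle <- max(sw_score_oracle(a, b), sw_score_oracle(a, revComp(b)))
    bios <- bios_local_score(a, b)
    if (oracle >= 5) {
      expect_identical(mine, as.integer(oracle))
      expect_identical(as.integer(bios), as.integer(oracle))
    } else {
      expect_identical(mine, 0L)
    }
  }
  # wider randomized sweep against the library oracle
  set.seed(24)
  for (k in 1:150) {
    a <- rnd_seq(sample(10:40, 1)); b <- rnd_seq(sample(10:40, 1))
    ours <- localAlign(setNames(a, "q"), setNames(b, "s"),
                       minScore = 5L, wordSize = 3L)
    mine <- if (nrow(ours)) max(ours$score) else 0L
    oracle <- bios_local_score(a, b)
    if (oracle >= 5) expect_identical(mine, as.integer(oracle))
    else expect_identical(mine, 0L)
  }
})

test_that("similarity windows match the exhaustive scan oracle", {
  # one mismatch in 60-mers leaves a 50-column window within threshold
  set.seed(25)
  a <- rnd_seq(60)
  b <- a
  substr(b, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(a, 30, 30))[1]
  expect_true(hasSimilarWindow(a, b, 50, 0.95)$found)
  expect_true(window_oracle(a, b, 50, 0.95))

  # identity is always similar to itself at any overlap within length
  expect_true(hasSimilarWindow(a, a, 60, 0.95)$found)

  # randomized agreement with the oracle, with and without planted windows
  for (k in 1:25) {
    x <- rnd_seq(60); y <- rnd_seq(60)
    if (k %% 3 == 0) {       # plant a 52-col window with 2 mismatches
      win <- substr(x, 5, 56)
      for (p in c(11, 37)) {
        substr(win, p, p) <-
          setdiff(c("A", "C", "G", "T"), substr(win, p, p))[1]
      }
      substr(y, 4, 55) <- win
    }
    if (k %% 5 == 0) y <- revComp(y)  # exercise the minus strand
    got <- hasSimilarWindow(x, y, 50, 0.95)$found
    expect_identical(got, window_oracle(x, y, 50, 0.95),
                     info = paste("case", k))
    # symmetry and joint reverse-complement invariance
    expect_identical(got, hasSimilarWindow(y, x, 50, 0.95)$found)
    expect_identical(got,
                     hasSimilarWindow(revComp(x), revComp(y), 50, 0.95)$found)
  }
})

test_that("the lossless seed length follows the pigeonhole bound", {
  # at exactly 50 columns and 95%: 2 mismatches, runs >= ceil(48/3) = 16
  expect_identical(losslessSeedLen(50, 50, 0.95), 16L)
  # 60-mers allow a 60-column window with 3 mismatches: ceil(57/4) = 15
  expect_identical(losslessSeedLen(50, 60, 0.95), 15L)
  # perfect identity: the window itself must match, capped at 16
  expect_identical(losslessSeedLen(25, 120, 1.0), 16L)
})

test_that("hit tables render 1-based closed BLAST-style rows", {
  set.seed(26)
  s <- rnd_seq(60)
  h <- localAlign(setNames(s, "q"), setNames(s, "s"), minScore = 10)
  h <- h[h$strand == "+", ][1, ]
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeHitTable(h, tf)
  fields <- strsplit(readLines(tf), "\t")[[1]]
  expect_identical(fields[1:2], c("q", "s"))
  expect_identical(fields[7:10], c("1", "60", "1", "60"))
  expect_identical(fields[3], "100.00")
})
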