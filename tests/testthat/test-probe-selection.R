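test_that("the flag filter removes strictly-above-a-quarter flag rates", {
  pcm <- make_pcm(sprintf("p%d", 1:7),
                  n = c(8, 8, 16, 16, 4, 4, 8),
                  pos = 0, flag = c(3, 2, 5, 4, 2, 1, 0))
  res <- filterFlagged(pcm)
  kept <- probeCalls(res$retained)$probe_id
  expect_setequal(kept, c("p2", "p4", "p6", "p7"))   # 2/8, 4/16, 1/4, 0/8
  expect_setequal(res$removed$probe_id, c("p1", "p3", "p5"))
  # smallest removal-triggering flag count at n = 16 is 5
  trig <- vapply(0:16, function(f) {
    nrow(filterFlagged(make_pcm("x", 16, 0, f))$removed) > 0
  }, logical(1))
  expect_identical(min(which(trig)) - 1L, 5L)
})

test_that("positivity needs at least three quarters of measurements", {
  pcm <- make_pcm(sprintf("p%d", 1:4), n = 8,
                  pos = c(6, 5, 8, 0), flag = 0)
  pos <- callPositive(pcm)
  expect_setequal(pos$probe_id, c("p1", "p3"))  # 6/8 = 0.75 makes the cut
})

make_positives <- function(seqs, target_id, orientation, mean_si,
                           target_seq = NULL) {
  if (is.null(target_seq)) {
    uniq <- setNames(vapply(unique(target_id), function(i) rnd_seq(120),
                            character(1)), unique(target_id))
    target_seq <- unname(uniq[target_id])
  }
  data.frame(probe_id = sprintf("%s|%s|0", target_id, orientation),
             target_id = target_id, orientation = orientation,
             seq = seqs, target_seq = target_seq, mean_si = mean_si,
             cv_si = 0.1, n_measurements = 8L, n_positive = 8L,
             n_flagged = 0L, stringsAsFactors = FALSE)
}

test_that("distinct, dissimilar positives pass selection unchanged", {
  set.seed(71)
  d <- make_positives(vapply(1:6, function(i) rnd_seq(60), character(1)),
                      sprintf("t%d", 1:6),
                      rep(c("sense", "antisense"), 3),
                      mean_si = seq(1000, 6000, by = 1000))
  v <- selectUnique(d)
  expect_identical(nrow(validatedProbes(v)), 6L)
  expect_identical(nrow(selectionLog(v)), 0L)
})

test_that("cross-orientation duplicates keep the brighter copy", {
  set.seed(72)
  shared <- rnd_seq(60)
  d <- make_positives(c(shared, shared), c("t1", "t2"),
                      c("sense", "antisense"), mean_si = c(5000, 3000))
  v <- selectUnique(d)
  e <- validatedProbes(v)
  expect_identical(nrow(e), 1L)
  expect_identical(e$orientation, "sense")
  lg <- selectionLog(v)
  expect_identical(lg$step, 4L)
  expect_identical(lg$probe_id, "t2|antisense|0")
})

test_that("highly similar probes lose the dimmer member at step 5", {
  set.seed(73)
  a <- rnd_seq(60)
  b <- paste0(rnd_seq(5), substr(a, 3, 52), rnd_seq(5))
  substr(b, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(b, 30, 30))[1]
  stopifnot(window_oracle(a, b, 50, 0.95))    # construction sanity
  d <- make_positives(c(a, b), c("t1", "t2"), c("sense", "sense"),
                      mean_si = c(4000, 2500))
  v <- selectUnique(d)
  expect_identical(validatedProbes(v)$probe_id, "t1|sense|0")
  lg <- selectionLog(v)
  expect_identical(lg$step, 5L)
  expect_match(lg$reason, "similar")
})

test_that("redundant targets collapse with their probes at step 3", {
  set.seed(74)
  tseq <- rnd_seq(120)
  d <- make_positives(c(substr(tseq, 1, 60), substr(tseq, 61, 120)),
                      c("tA", "tB"), c("sense", "sense"),
                      mean_si = c(2000, 7000),
                      target_seq = c(tseq, tseq))
  v <- selectUnique(d)
  e <- validatedProbes(v)
  expect_identical(nrow(e), 1L)
  expect_identical(e$target_id, "tB")          # brighter probe's target
  expect_identical(selectionLog(v)$step, 3L)
})

test_that("selection conserves probes and is idempotent", {
  set.seed(75)
  targets <- simulateTranscriptome(120, c(100, 400), seed = 75)
  cfg <- truthConfig(seed = 75)
  res <- runProbePipeline(targets, cfg,
                          spikes = spikeInSet(replicates = 10L))
  v <- res$validated
  e <- validatedProbes(v); lg <- selectionLog(v)
  # every positive probe ends in the set or the log, exactly once
  ids <- c(e$probe_id, lg$probe_id)
  expect_setequal(ids, res$positives$probe_id)
  expect_identical(anyDuplicated(ids), 0L)
  # idempotence: re-selecting the survivors changes nothing
  again <- selectUnique(joinProbeData(
    probeCalls(res$callMatrix)[match(e$probe_id,
                                     probeCalls(res$callMatrix)$probe_id), ],
    res$probes, targets))
  expect_identical(sort(validatedProbes(again)$probe_id), sort(e$probe_id))
  expect_identical(nrow(selectionLog(again)), 0L)
  # final-set audit: the exhaustive scan finds no similar pair
  expect_identical(nrow(auditSimilarPairs(setNames(e$seq, e$probe_id))), 0L)
  validObject(v)
})

test_that("selection rejects incomplete inputs", {
  d <- make_positives(rnd_seq(60), "t1", "sense", 1000)
  expect_error(selectUnique(d[, setdiff(names(d), "target_seq")]),
               "target_seq")
  d$mean_si <- NA_real_
  expect_error(selectUnique(d), "missing")
})

test_that("summaries reproduce the category arithmetic", {
  expect_identical(probeSetTotal(c(sense60 = 33740, antisense60 = 28133,
                                   mer40 = 1668)), 63541L)
  expect_equal(orientationSharePercent(33740, 28133), 54.5)
  expect_equal(orientationSharePercent(28133, 33740), 45.5)
  expect_equal(coveragePercent(10.4, 700), 1.5)
  # empty set: all-zero summary
  empty <- new("ValidatedProbeSet",
               entries = data.frame(probe_id = character(),
                                    target_id = character(),
                                    orientation = character(),
                                    probe_length = integer(),
                                    seq = character(),
                                    target_length = integer(),
                                    mean_si = numeric(), cv_si = numeric()),
               log = data.frame(), config = list())
  s <- summarizeProbeSet(empty)
  expect_identical(s$n_total, 0L)
  expect_identical(s$targeted_bases, 0L)
})
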