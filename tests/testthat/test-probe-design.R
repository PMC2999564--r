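test_that("targets are classified into the length classes", {
  expect_equal(classifyTarget(50)[c("probe_length", "probes_per_target")],
               list(probe_length = 40L, probes_per_target = 1L))
  expect_identical(classifyTarget(59)$probe_length, 40L)
  expect_identical(classifyTarget(60)$probe_length, 60L)
  expect_identical(classifyTarget(150)$probes_per_target, 1L)  # boundary
  expect_identical(classifyTarget(151)$probes_per_target, 2L)
  expect_identical(classifyTarget(200)$probes_per_target, 2L)
  expect_identical(classifyTarget(300)$probes_per_target, 2L)  # boundary
  expect_identical(classifyTarget(350)$probes_per_target, 4L)
  expect_true(classifyTarget(39)$rejected)
  expect_identical(classifyTarget(200)$method, "best_distribution")
  # an SSH-style override wins regardless of length
  ov <- designRule(60, 2, "best_distribution")
  expect_identical(classifyTarget(80, sourceOverride = ov),
                   ov)
})

test_that("design rules enforce their own invariants", {
  expect_error(designRule(60, 2, "best_probe"), "best_distribution")
  expect_error(designRule(40, 2, "best_distribution"), "single")
  expect_error(designRule(50, 1, "best_probe"))
})

test_that("window scores match the stated formula", {
  # balanced GC, no long runs, no hairpin: every penalty vanishes
  # ({A,G} words share nothing with their {C,T} reverse complement)
  expect_equal(scoreWindow(strrep("AAGG", 15)), 0)
  # A*60: GC term -0.5, homopolymer -0.05 * 56, no self-complement
  expect_equal(scoreWindow(strrep("A", 60)), -3.3)
  # more than 10% N makes a window ineligible
  expect_identical(scoreWindow(paste0(strrep("N", 7), strrep("ACGT", 13),
                                      "A")), -Inf)
  # randomized agreement with an independent base-R computation, and
  # reverse-complement invariance of the score
  set.seed(41)
  for (k in 1:20) {
    w <- rnd_seq(60, c("A", "C", "G", "T", if (k %% 4 == 0) "N"))
    expect_equal(scoreWindow(w), score_window_oracle(w), info = w)
    expect_equal(scoreWindow(w), scoreWindow(revComp(w)))
  }
})

test_that("best-probe design picks the top-scoring window deterministically", {
  set.seed(42)
  # length-60 target admits exactly one window: the full sequence
  t60 <- setNames(rnd_seq(60), "t60")
  p <- designProbes(t60, orientation = "sense")
  expect_identical(nrow(p), 1L)
  expect_identical(p$start, 0L)
  expect_identical(p$seq, unname(t60))

  # single-probe target: start equals the argmax of the per-window scores
  tgt <- setNames(rnd_seq(140), "t140")
  p1 <- designProbes(tgt, orientation = "sense")
  scores <- vapply(0:(140 - 60), function(s)
    scoreWindow(substr(tgt, s + 1, s + 60)), numeric(1))
  expect_identical(p1$start, which.max(scores) - 1L)
})

test_that("best-distribution design places one probe per segment", {
  set.seed(43)
  tgt <- setNames(rnd_seq(400), "t400")
  p <- designProbes(tgt, orientation = "sense")
  expect_identical(nrow(p), 4L)
  seg <- findInterval(p$start, c(0, 100, 200, 300, 400),
                      rightmost.closed = TRUE)
  expect_identical(seg, 1:4)
  expect_identical(anyDuplicated(p$seq), 0L)
  # within each segment the fully-contained window with the best score wins
  for (i in 1:4) {
    cand <- seq.int((i - 1) * 100, i * 100 - 60)
    sc <- vapply(cand, function(s)
      scoreWindow(substr(tgt, s + 1, s + 60)), numeric(1))
    expect_identical(p$start[i], cand[which.max(sc)])
  }
})

test_that("antisense probes are substrings of the reverse complement", {
  set.seed(44)
  tgt <- setNames(rnd_seq(250), "t")
  p <- designProbes(tgt, orientation = "both")
  rc <- revComp(tgt[[1]])
  for (i in seq_len(nrow(p))) {
    src <- if (p$orientation[i] == "sense") tgt[[1]] else rc
    expect_identical(substr(src, p$start[i] + 1, p$start[i] + p$length[i]),
                     p$seq[i])
  }
  # probes-per-target honors the rule whenever the target is long enough
  set.seed(45)
  for (L in c(60, 100, 151, 280, 301, 500)) {
    rule <- classifyTarget(L)
    d <- designProbes(setNames(rnd_seq(L), "x"), orientation = "sense")
    expect_identical(nrow(d), rule$probes_per_target)
  }
})

test_that("short or rejected targets design no probes, with a warning", {
  expect_warning(p <- designProbes(setNames(strrep("A", 30), "tiny")),
                 "rejected")
  expect_identical(nrow(p), 0L)
})

test_that("exact deduplication keeps one probe per distinct sequence", {
  set.seed(46)
  block <- rnd_seq(200)
  # two targets sharing their sequence: identical probes designed twice
  targets <- Biostrings::DNAStringSet(c(tA = block, tB = block,
                                        tC = rnd_seq(200)))
  S4Vectors::mcols(targets) <- S4Vectors::DataFrame(
    source = c("g1", "g2", "g2"))
  probes <- designProbeSet(targets, orientation = "sense")
  dd <- dedupExact(probes)
  expect_identical(nrow(dd), length(unique(probes$seq)))
  expect_identical(attr(dd, "n_removed"),
                   nrow(probes) - length(unique(probes$seq)))
  # group priority: the surviving copy of each duplicate is from group g1
  dup_seqs <- probes$seq[duplicated(probes$seq)]
  expect_true(all(dd$group[dd$seq %in% dup_seqs] == "g1"))
  # all-distinct input passes through unchanged
  p3 <- probes[!duplicated(probes$seq), ]
  expect_identical(nrow(dedupExact(p3)), nrow(p3))
})

test_that("array layout accounting conserves spots", {
  # the 244K format: 243,504 spots, 2,105 controls, 241,399 features
  probes <- data.frame(probe_id = sprintf("p%06d", 1:215270))
  d <- buildLayout(probes)
  expect_identical(featureCapacity(d), 241399L)
  expect_identical(d@nUnique, 215270L)
  expect_identical(d@nDuplicateFill, 26129L)
  expect_identical(d@controlSpots + d@nUnique + d@nDuplicateFill,
                   d@totalSpots)
  expect_identical(nrow(arrayFeatures(d)), 241399L)

  # exact fill leaves no duplicates
  d2 <- buildLayout(data.frame(probe_id = sprintf("q%06d", 1:241399)))
  expect_identical(d2@nDuplicateFill, 0L)

  # overflow is a capacity error naming the overage
  expect_error(buildLayout(data.frame(probe_id = sprintf("r%06d", 1:241400))),
               "overflow")

  # duplicate fill cycles through probes in input order
  d3 <- buildLayout(data.frame(probe_id = c("a", "b", "c")),
                    totalSpots = 10L, controlSpots = 2L)
  ft <- arrayFeatures(d3)
  expect_identical(ft$probe_id, c("a", "b", "c", "a", "b", "c", "a", "b"))
  expect_identical(max(ft$replicate_index[ft$probe_id == "a"]), 3L)
})
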