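spike3 <- spikeInSet(concentrations = c(10, 20, 40), replicates = 3L)

spots_df <- function(probe_id, si, array = "A1", pmt = 400L) {
  data.frame(probe_id = probe_id, array_id = array, pmt = pmt,
             replicate = stats::ave(seq_along(probe_id), probe_id,
                                    FUN = seq_along),
             si = si, is_control = TRUE, stringsAsFactors = FALSE)
}

test_that("the threshold is mean + 2 SD of the three lowest spikes", {
  # zero variance: threshold equals the common value
  sp0 <- spots_df(rep(spike3$probe_id, each = 3), rep(100, 9))
  cal0 <- calibrateThreshold(sp0, spike3)
  expect_equal(callingThreshold(cal0), 100)

  # {90, 100, 110} replicates per species: direct arithmetic
  vals <- rep(c(90, 100, 110), times = 3)
  sp1 <- spots_df(rep(spike3$probe_id, each = 3), vals)
  cal1 <- calibrateThreshold(sp1, spike3)
  expect_equal(callingThreshold(cal1), mean(vals) + 2 * sd(vals))

  # translation equivariance: adding c shifts the threshold by c
  sp2 <- sp1; sp2$si <- sp2$si + 57.5
  expect_equal(callingThreshold(calibrateThreshold(sp2, spike3)),
               callingThreshold(cal1) + 57.5)
})

test_that("the three lowest species are chosen by observed signal", {
  sp10 <- spikeInSet(replicates = 4L)
  si <- rep(sp10$concentration, each = 4) * 2      # signal ~ concentration
  spots <- spots_df(rep(sp10$probe_id, each = 4), si)
  cal <- calibrateThreshold(spots, sp10)
  expect_identical(sort(cal@lowestSpikeIds), sp10$spike_id[1:3])
  pooled <- si[rep(sp10$probe_id, each = 4) %in% cal@lowestSpikeIds]
  expect_equal(callingThreshold(cal), mean(pooled) + 2 * sd(pooled))
})

test_that("degenerate spike data are rejected", {
  two <- spikeInSet(concentrations = c(10, 20, 40), replicates = 3L)
  spots <- spots_df(rep(two$probe_id[1:2], each = 3), rep(50, 6))
  expect_error(calibrateThreshold(spots, two), "at least 3")
  one_rep <- spots_df(c(two$probe_id, two$probe_id[1:2]), rep(50, 5))
  expect_error(calibrateThreshold(one_rep, two), "replicate")
})

test_that("spot calls respect both boundaries and are monotone", {
  cal <- new("CalibrationResult", arrayId = "A1", pmt = 400L,
             threshold = 150, lowestSpikeIds = c("a", "b", "c"),
             saturationLevel = 65000)
  expect_identical(callSpot(65000, cal), "saturated")
  expect_identical(callSpot(64999.99, cal), "present")
  expect_identical(callSpot(150, cal), "absent")     # at threshold: absent
  expect_identical(callSpot(150.01, cal), "present")
  expect_identical(callSpot(-25, cal), "absent")     # negative SI tolerated
  si <- sort(runif(100, -100, 70000))
  calls <- callSpot(si, cal)
  ord <- match(calls, c("absent", "present", "saturated"))
  expect_true(all(diff(ord) >= 0))                   # raising SI never demotes
})

test_that("negative controls are checked against the spike floor", {
  sp <- spikeInSet(concentrations = c(10, 20, 40), replicates = 3L)
  good <- rbind(spots_df(rep(sp$probe_id, each = 3), rep(c(10, 20, 40),
                                                         each = 3)),
                spots_df(rep("negctrl", 4), c(1, 2, 3, 4)))
  res <- checkNegativeControls(good, sp)
  expect_true(all(res$pass))
  bad <- good
  bad$si[bad$probe_id == "negctrl"][1] <- 99     # above the lowest median
  res2 <- checkNegativeControls(bad, sp)
  expect_false(all(res2$pass))
  expect_identical(nrow(attr(res2, "failed")), 1L)
  # no negative controls: vacuous pass with a warning
  expect_warning(
    res3 <- checkNegativeControls(good[good$probe_id != "negctrl", ], sp),
    "vacuous")
  expect_true(all(res3$pass))
})

test_that("call tabulation matches the 4/8/16 measurement structure", {
  targets <- simulateTranscriptome(25, c(100, 200), seed = 61)
  cfg <- truthConfig(seed = 61)
  probes <- dedupExact(designProbeSet(targets))
  design <- buildLayout(probes, totalSpots = nrow(probes) + 3L + 700L,
                        controlSpots = 700L)  # 3 duplicate-fill spots
  truth <- drawTruth(targets, cfg)
  sp <- spikeInSet()
  m <- simulateHybridization(probes, truth, cfg, sp, design = design,
                             nArrays = 4L)
  pcm <- tabulateCalls(m, calibrateArrays(m, sp))
  calls <- probeCalls(pcm)
  # 4 arrays x 2 gains = 8 measurements; duplicate-filled probes get 16
  expect_setequal(unique(calls$n_measurements), c(8L, 16L))
  expect_identical(sum(calls$n_measurements == 16L), 3L)
  # spot conservation: every non-control instance is one measurement
  expect_identical(sum(calls$n_measurements), sum(!m$is_control))
  expect_true(all(calls$n_positive + calls$n_flagged <=
                    calls$n_measurements))
  # a matched-orientation probe of an expressed target is all-positive
  tr <- truth[match(probes$target_id, truth$target_id), ]
  matched <- probes$probe_id[tr$expressed &
                               probes$orientation == tr$orientation]
  frac <- calls$n_positive[match(matched, calls$probe_id)] /
    calls$n_measurements[match(matched, calls$probe_id)]
  expect_gt(mean(frac >= 0.75), 0.9)
})

test_that("probes without spots get zero rows only on request", {
  spots <- data.frame(probe_id = "p1", array_id = "A1", pmt = 400L,
                      replicate = 1L, si = 500, is_control = FALSE)
  cal <- new("CalibrationResult", arrayId = "A1", pmt = 400L,
             threshold = 100, lowestSpikeIds = c("a", "b", "c"),
             saturationLevel = 65000)
  expect_warning(
    pcm <- tabulateCalls(spots, cal, probeUniverse = c("p1", "p2")),
    "no spot")
  calls <- probeCalls(pcm)
  expect_identical(calls$n_measurements[calls$probe_id == "p2"], 0L)
  expect_identical(calls$n_positive[calls$probe_id == "p1"], 1L)
})

test_that("mean SI is computed over non-flagged measurements only", {
  spots <- data.frame(probe_id = "p1", array_id = "A1", pmt = 400L,
                      replicate = 1:4, si = c(66000, 1000, 2000, 3000),
                      is_control = FALSE)
  cal <- new("CalibrationResult", arrayId = "A1", pmt = 400L,
             threshold = 100, lowestSpikeIds = c("a", "b", "c"),
             saturationLevel = 65000)
  calls <- probeCalls(tabulateCalls(spots, cal))
  expect_identical(calls$n_flagged, 1L)
  expect_identical(calls$n_positive, 3L)
  expect_equal(calls$mean_si, 2000)
  expect_equal(calls$cv_si, sd(c(1000, 2000, 3000)) / 2000)
})
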