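#' Run the design-hybridize-call-select pipeline on a target collection
#'
#' Convenience orchestration of the whole workflow on simulated
#' hybridizations: design probes in both orientations, deduplicate, lay
#' them out (a compact layout by default: every unique probe plus a small
#' duplicate fill plus the control block), draw the expression truth,
#' simulate the arrays at both gains, calibrate each scan from its
#' spike-ins, tabulate calls, then apply the six-step selection.
#'
#' @param targets [Biostrings::DNAStringSet] or named character vector.
#' @param config a [truthConfig()].
#' @param spikes a [spikeInSet()].
#' @param selection a [selectionConfig()].
#' @param nArrays,pmts scanning design (defaults 4 arrays, gains 400/500).
#' @param layoutFill duplicate-fill spots in the compact layout
#'   (default 200).
#' @param nNegControls negative-control spots per array (default 100).
#' @param overrides per-source design-rule overrides (see
#'   [designProbeSet()]).
#' @return list with elements probes, design, truth, measurements,
#'   calibrations, callMatrix, flaggedRemoved, positives, validated.
#' @export
runProbePipeline <- function(targets, config, spikes = spikeInSet(),
                             selection = selectionConfig(),
                             nArrays = 4L, pmts = c(400L, 500L),
                             layoutFill = 200L, nNegControls = 100L,
                             overrides = list()) {
  probes <- designProbeSet(targets, orientation = "both",
                           overrides = overrides)
  probes <- dedupExact(probes)
  controls <- sum(spikes$replicates) + nNegControls
  design <- buildLayout(probes,
                        totalSpots = nrow(probes) + layoutFill + controls,
                        controlSpots = controls)
  truth <- drawTruth(targets, config)
  meas <- simulateHybridization(probes, truth, config, spikes,
                                design = design, nArrays = nArrays,
                                pmts = pmts, nNegControls = nNegControls)
  cals <- calibrateArrays(meas, spikes)
  pcm <- tabulateCalls(meas, cals)
  ff <- filterFlagged(pcm, selection)
  pos <- callPositive(ff$retained, selection)
  joined <- joinProbeData(pos, probes, targets)
  validated <- selectUnique(joined, selection)
  list(probes = probes, design = design, truth = truth,
       measurements = meas, calibrations = cals, callMatrix = pcm,
       flaggedRemoved = ff$removed, positives = pos,
       validated = validated)
}

#' Compare a validated probe set against the simulation truth
#'
#' @param validated a [ValidatedProbeSet-class].
#' @param truth data.frame from [drawTruth()].
#' @return list(n_expressed, n_recovered, recovery_fraction,
#'   n_from_unexpressed): an expressed target counts as recovered when the
#'   validated set contains a probe for it in the true orientation.
#' @export
orientationRecovery <- function(validated, truth) {
  e <- validatedProbes(validated)
  expressed <- truth[truth$expressed, , drop = FALSE]
  i <- match(expressed$target_id, e$target_id)
  recovered <- !is.na(i) & e$orientation[i] == expressed$orientation
  unexpr <- truth$target_id[!truth$expressed]
  list(n_expressed = nrow(expressed),
       n_recovered = sum(recovered),
       recovery_fraction = if (nrow(expressed)) mean(recovered) else NA_real_,
       n_from_unexpressed = sum(e$target_id %in% unexpr))
}
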