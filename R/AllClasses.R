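#' Scoring parameters for nucleotide local alignment
#'
#' Match/mismatch rewards and affine gap penalties in the BLASTN convention
#' (a gap of length g costs `gapOpen + g * gapExtend`; penalties are
#' negative), plus the background base composition used by the
#' Karlin-Altschul statistics.
#'
#' @slot match positive integer match reward.
#' @slot mismatch negative integer mismatch penalty.
#' @slot gapOpen,gapExtend negative integer gap penalties.
#' @slot composition numeric(4), background frequencies of A, C, G, T
#'   summing to 1.
#' @exportClass ScoringParams
setClass("ScoringParams",
  representation(match = "integer", mismatch = "integer",
                 gapOpen = "integer", gapExtend = "integer",
                 composition = "numeric"))

setValidity("ScoringParams", function(object) {
  msg <- character()
  if (object@match <= 0L) msg <- c(msg, "match reward must be positive")
  if (object@mismatch >= 0L) msg <- c(msg, "mismatch penalty must be negative")
  if (object@gapOpen >= 0L || object@gapExtend >= 0L)
    msg <- c(msg, "gap penalties must be negative")
  if (length(object@composition) != 4L ||
      abs(sum(object@composition) - 1) > 1e-8 ||
      any(object@composition <= 0))
    msg <- c(msg, "composition must be 4 positive frequencies summing to 1")
  if (length(msg) == 0L) {
    pm <- sum(object@composition^2)
    es <- pm * object@match + (1 - pm) * object@mismatch
    if (es >= 0) msg <- c(msg, "expected per-column score must be negative")
  }
  if (length(msg)) msg else TRUE
})

#' Karlin-Altschul parameters for ungapped local alignment statistics
#'
#' @slot lambda positive root of the ungapped Karlin-Altschul equation.
#' @slot K the Karlin-Altschul search-space constant.
#' @slot H relative entropy of the aligned-column score (nats/position).
#' @exportClass KarlinAltschulParams
setClass("KarlinAltschulParams",
  representation(lambda = "numeric", K = "numeric", H = "numeric"))

setValidity("KarlinAltschulParams", function(object) {
  if (object@lambda <= 0 || object@K <= 0) "lambda and K must be positive"
  else TRUE
})

#' Assembly completeness report
#'
#' Within-assembly redundancy tallies: for every sequence aligned against all
#' others in the same assembly, the number of significant hits (E at or below
#' the threshold) and the number of sequences carrying an ungapped overlap of
#' at least `minOverlap` columns at 100% and at >95% identity. The identity
#' categories are nested: a sequence with a perfect overlap also counts in
#' the >95% column.
#'
#' @slot counts data.frame with one row per source class plus a Total row:
#'   columns class, n_sequences, n_significant_hits, n_identical,
#'   n_near_identical.
#' @slot eThreshold,minOverlap the parameters used.
#' @exportClass CompletenessReport
setClass("CompletenessReport",
  representation(counts = "data.frame", eThreshold = "numeric",
                 minOverlap = "integer"))

#' Assembly correctness report
#'
#' Agreement of an assembly with reference (e.g. Sanger) EST sets: per
#' reference set, the number of assembly sequences with a significant best
#' hit and the number whose best hit covers the full length (the shorter of
#' query and subject, at least `minFullLength` bases) at the per-set identity
#' threshold.
#'
#' @slot counts data.frame with one row per (class, reference set):
#'   columns class, ref_set, n_sequences, n_significant, n_full_length,
#'   identity_threshold.
#' @slot minFullLength,eThreshold parameters used.
#' @exportClass CorrectnessReport
setClass("CorrectnessReport",
  representation(counts = "data.frame", minFullLength = "integer",
                 eThreshold = "numeric"))

#' Microarray layout accounting
#'
#' Placement of a probe collection on a fixed-format array: every unique
#' probe once, remaining feature capacity filled by cycling through the
#' probes in input order, plus the control spots.
#'
#' @slot totalSpots,controlSpots integer spot counts.
#' @slot nUnique,nDuplicateFill integer feature accounting.
#' @slot features data.frame(probe_id, replicate_index).
#' @exportClass ArrayDesign
setClass("ArrayDesign",
  representation(totalSpots = "integer", controlSpots = "integer",
                 nUnique = "integer", nDuplicateFill = "integer",
                 features = "data.frame"))

setValidity("ArrayDesign", function(object) {
  if (object@totalSpots !=
      object@controlSpots + object@nUnique + object@nDuplicateFill)
    return("spot accounting violated: controls + unique + duplicates != total")
  TRUE
})

#' Per-array, per-gain spike-in calibration
#'
#' @slot arrayId,pmt identity of the scan.
#' @slot threshold the present/absent threshold in background-subtracted SI
#'   units (mean + 2 SD of the pooled replicates of the three lowest
#'   spike-in species).
#' @slot lowestSpikeIds the three spike species used.
#' @slot saturationLevel SI at or above which a spot is saturated.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(arrayId = "character", pmt = "integer",
                 threshold = "numeric", lowestSpikeIds = "character",
                 saturationLevel = "numeric"))

setValidity("CalibrationResult", function(object) {
  if (object@saturationLevel <= object@threshold)
    return("saturation level must exceed the calling threshold")
  TRUE
})

#' Per-probe tally of spot calls
#'
#' One row per probe: number of measurements (every spot instance across
#' arrays, gains and duplicate-fill replicates), how many were called
#' present (positive) and saturated (flagged), and the mean and coefficient
#' of variation of SI over non-flagged measurements.
#'
#' @slot calls data.frame(probe_id, n_measurements, n_positive, n_flagged,
#'   mean_si, cv_si).
#' @exportClass ProbeCallMatrix
setClass("ProbeCallMatrix", representation(calls = "data.frame"))

setValidity("ProbeCallMatrix", function(object) {
  d <- object@calls
  need <- c("probe_id", "n_measurements", "n_positive", "n_flagged",
            "mean_si", "cv_si")
  if (!all(need %in% names(d))) return("missing call-matrix columns")
  if (any(d$n_positive + d$n_flagged > d$n_measurements))
    return("n_positive + n_flagged exceeds n_measurements")
  if (anyDuplicated(d$probe_id)) return("duplicate probe ids")
  TRUE
})

#' The validated one-probe-per-target set
#'
#' Output of the six-step selection: pairwise-distinct probe sequences,
#' pairwise-distinct targets, no probe pair similar at the configured
#' window thresholds, and every entry positive under the positivity rule.
#' The provenance log records, for every removed probe, the selection step
#' (1-6) and the reason.
#'
#' @slot entries data.frame(probe_id, target_id, orientation, probe_length,
#'   seq, target_length, mean_si, cv_si).
#' @slot log data.frame(probe_id, step, reason).
#' @slot config the [selectionConfig()] used.
#' @exportClass ValidatedProbeSet
setClass("ValidatedProbeSet",
  representation(entries = "data.frame", log = "data.frame",
                 config = "list"))

setValidity("ValidatedProbeSet", function(object) {
  e <- object@entries
  msg <- character()
  if (nrow(e)) {
    if (anyDuplicated(e$seq)) msg <- c(msg, "probe sequences not distinct")
    if (anyDuplicated(e$target_id)) msg <- c(msg, "target ids not distinct")
  }
  if (length(msg)) msg else TRUE
})
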