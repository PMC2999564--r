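#' @name accessors
#' @title Accessors for estarray result objects
#'
#' @description Small read-only accessors so downstream code never touches
#' slots directly: `reportCounts()` returns the tabular body of a QC report,
#' `probeCalls()` the per-probe call table, `validatedProbes()` and
#' `selectionLog()` the two faces of a [ValidatedProbeSet-class], and
#' `featureCapacity()` / `arrayFeatures()` the accounting of an
#' [ArrayDesign-class].
#'
#' @param x an estarray S4 object.
#' @return A `data.frame` (or integer for `featureCapacity`).
NULL

#' @rdname accessors
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))

#' @rdname accessors
#' @export
setMethod("reportCounts", "CompletenessReport", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("reportCounts", "CorrectnessReport", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("probeCalls", function(x) standardGeneric("probeCalls"))

#' @rdname accessors
#' @export
setMethod("probeCalls", "ProbeCallMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("validatedProbes", function(x) standardGeneric("validatedProbes"))

#' @rdname accessors
#' @export
setMethod("validatedProbes", "ValidatedProbeSet", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))

#' @rdname accessors
#' @export
setMethod("selectionLog", "ValidatedProbeSet", function(x) x@log)

#' @rdname accessors
#' @export
setGeneric("featureCapacity", function(x) standardGeneric("featureCapacity"))

#' @rdname accessors
#' @export
setMethod("featureCapacity", "ArrayDesign",
          function(x) x@totalSpots - x@controlSpots)

#' @rdname accessors
#' @export
setGeneric("arrayFeatures", function(x) standardGeneric("arrayFeatures"))

#' @rdname accessors
#' @export
setMethod("arrayFeatures", "ArrayDesign", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("callingThreshold", function(x) standardGeneric("callingThreshold"))

#' @rdname accessors
#' @export
setMethod("callingThreshold", "CalibrationResult", function(x) x@threshold)

setMethod("show", "ScoringParams", function(object) {
  cat("ScoringParams: match ", object@match, ", mismatch ", object@mismatch,
      ", gap ", object@gapOpen, "/", object@gapExtend, "\n", sep = "")
})

setMethod("show", "KarlinAltschulParams", function(object) {
  cat(sprintf("KarlinAltschulParams: lambda %.6f, K %.6f, H %.6f\n",
              object@lambda, object@K, object@H))
})

setMethod("show", "CompletenessReport", function(object) {
  cat("Assembly completeness test (E <=", format(object@eThreshold),
      ", overlap >=", object@minOverlap, "columns)\n")
  cat("Identity categories are nested: 100% windows also count as >95%.\n")
  print(object@counts, row.names = FALSE)
})

setMethod("show", "CorrectnessReport", function(object) {
  cat("Assembly correctness test (E <=", format(object@eThreshold),
      ", full length >=", object@minFullLength, "bases)\n")
  print(object@counts, row.names = FALSE)
})

setMethod("show", "ArrayDesign", function(object) {
  cat("ArrayDesign:", object@totalSpots, "spots =",
      object@controlSpots, "controls +", object@nUnique, "unique probes +",
      object@nDuplicateFill, "duplicate fill\n")
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "Calibration %s / PMT %d: threshold %.2f (spikes %s), saturation %.0f\n",
    object@arrayId, object@pmt, object@threshold,
    paste(object@lowestSpikeIds, collapse = ","), object@saturationLevel))
})

setMethod("show", "ProbeCallMatrix", function(object) {
  cat("ProbeCallMatrix:", nrow(object@calls), "probes,",
      sum(object@calls$n_measurements), "measurements\n")
  print(head(object@calls), row.names = FALSE)
})

setMethod("show", "ValidatedProbeSet", function(object) {
  e <- object@entries
  cat("ValidatedProbeSet:", nrow(e), "validated probes (",
      sum(e$orientation == "sense"), "sense /",
      sum(e$orientation == "antisense"), "antisense ),",
      nrow(object@log), "removals logged\n")
})
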