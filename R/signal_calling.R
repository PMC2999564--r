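#' Calibrate the present/absent threshold from spike-in spots
#'
#' For one array at one PMT gain: the three spike-in species with the
#' lowest median replicate SI are selected (by observed signal, not nominal
#' concentration, so calibration works even when concentrations are
#' unknown), and the threshold is the mean plus twice the sample standard
#' deviation (n-1 denominator) of the pooled replicate SIs of those three
#' species. Replicates are the observable variance source, hence the SD is
#' taken over the pooled replicates rather than over the three species
#' means.
#'
#' @param spots data.frame of spot measurements for a single array x PMT
#'   combination (columns probe_id, si at minimum).
#' @param spikes a [spikeInSet()].
#' @param saturationLevel SI at or above which a spot is saturated
#'   (default 65000).
#' @return A [CalibrationResult-class].
#' @export
calibrateThreshold <- function(spots, spikes, saturationLevel = 65000) {
  ss <- spots[spots$probe_id %in% spikes$probe_id, , drop = FALSE]
  present <- intersect(spikes$probe_id, unique(ss$probe_id))
  if (length(present) < 3L)
    stop("calibration requires at least 3 spike-in species; found ",
         length(present))
  reps <- table(ss$probe_id)[present]
  if (any(reps < 2L))
    stop("calibration requires >= 2 replicate spots per spike species")
  med <- vapply(present, function(p) median(ss$si[ss$probe_id == p]),
                numeric(1))
  lowest <- present[order(med, present)][1:3]
  pooled <- ss$si[ss$probe_id %in% lowest]
  thr <- mean(pooled) + 2 * sd(pooled)
  aid <- if ("array_id" %in% names(spots)) unique(spots$array_id) else "A"
  pmt <- if ("pmt" %in% names(spots)) unique(spots$pmt) else NA_integer_
  if (length(aid) != 1L || length(pmt) != 1L)
    stop("calibrateThreshold() expects spots from a single array x PMT scan")
  new("CalibrationResult", arrayId = as.character(aid),
      pmt = as.integer(pmt), threshold = thr,
      lowestSpikeIds = lowest, saturationLevel = saturationLevel)
}

#' Calibrate every array x PMT scan in a measurement table
#'
#' @param measurements data.frame from [simulateHybridization()] or
#'   [readGprLike()].
#' @param spikes a [spikeInSet()].
#' @param saturationLevel see [calibrateThreshold()].
#' @return list of [CalibrationResult-class], named `"<array>.<pmt>"`.
#' @export
calibrateArrays <- function(measurements, spikes, saturationLevel = 65000) {
  key <- interaction(measurements$array_id, measurements$pmt, drop = TRUE)
  out <- lapply(split(measurements, key), calibrateThreshold,
                spikes = spikes, saturationLevel = saturationLevel)
  out
}

#' Per-scan calibration table
#'
#' @param calibrations list from [calibrateArrays()].
#' @return data.frame(array_id, pmt, threshold, saturation_level,
#'   lowest_spikes).
#' @export
calibrationTable <- function(calibrations) {
  do.call(rbind, lapply(calibrations, function(cal) data.frame(
    array_id = cal@arrayId, pmt = cal@pmt, threshold = cal@threshold,
    saturation_level = cal@saturationLevel,
    lowest_spikes = paste(cal@lowestSpikeIds, collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Call a spot present, absent or saturated
#'
#' A spot at or above the saturation level is `saturated` (unreliable,
#' flagged); otherwise at or below the threshold it is `absent`
#' (conservative boundary: a spot exactly at the threshold is absent);
#' otherwise `present`. Vectorized over `si`.
#'
#' @param si numeric background-subtracted signal intensities (may be
#'   negative).
#' @param cal a [CalibrationResult-class], or a numeric threshold.
#' @param saturationLevel used when `cal` is a bare threshold.
#' @return character vector in {"absent", "present", "saturated"}.
#' @export
callSpot <- function(si, cal, saturationLevel = 65000) {
  if (is(cal, "CalibrationResult")) {
    thr <- cal@threshold
    saturationLevel <- cal@saturationLevel
  } else {
    thr <- cal
  }
  ifelse(si >= saturationLevel, "saturated",
         ifelse(si <= thr, "absent", "present"))
}

#' Check negative-control spots against the spike-in floor
#'
#' Fails (with a listing) any negative-control spot whose SI exceeds the
#' minimum spike-in median of the same scan: background should never
#' out-shine the dimmest calibration species.
#'
#' @param measurements measurement table including control spots (probes
#'   named `"negctrl"` are treated as negative controls).
#' @param spikes a [spikeInSet()].
#' @return data.frame(array_id, pmt, n_controls, n_failed, pass) with
#'   attribute `failed` listing offending spots; empty control sets pass
#'   vacuously with a warning.
#' @export
checkNegativeControls <- function(measurements, spikes) {
  key <- interaction(measurements$array_id, measurements$pmt, drop = TRUE)
  pieces <- split(measurements, key)
  failed <- list()
  rows <- lapply(pieces, function(m) {
    neg <- m[m$probe_id == "negctrl", , drop = FALSE]
    sp <- m[m$probe_id %in% spikes$probe_id, , drop = FALSE]
    floor_si <- min(vapply(split(sp$si, sp$probe_id), median, numeric(1)))
    if (!nrow(neg)) {
      warning("no negative-control spots in scan ", unique(m$array_id),
              "/", unique(m$pmt), ": vacuous pass")
    }
    bad <- neg[neg$si > floor_si, , drop = FALSE]
    if (nrow(bad)) failed[[length(failed) + 1L]] <<- bad
    data.frame(array_id = unique(m$array_id), pmt = unique(m$pmt),
               n_controls = nrow(neg), n_failed = nrow(bad),
               pass = nrow(bad) == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "failed") <- if (length(failed)) do.call(rbind, failed)
                         else NULL
  out
}

#' Tabulate spot calls into a per-probe call matrix
#'
#' Every non-control spot instance (including duplicate-fill replicates) is
#' one measurement: `present` counts as positive, `saturated` as flagged,
#' `absent` as neither, so a probe on 4 arrays at 2 gains with no
#' duplicates has 8 measurements and one duplicate fill doubles that to 16.
#' `mean_si` and `cv_si` are computed over non-flagged measurements.
#'
#' @param measurements measurement table.
#' @param calibrations list from [calibrateArrays()] (or a single
#'   [CalibrationResult-class] when the table holds one scan).
#' @param probeUniverse optional character vector of all probe ids that
#'   should appear; probes without any spot get an all-zero row with a
#'   warning.
#' @return A [ProbeCallMatrix-class].
#' @export
tabulateCalls <- function(measurements, calibrations, probeUniverse = NULL) {
  if (is(calibrations, "CalibrationResult"))
    calibrations <- setNames(
      list(calibrations),
      paste(calibrations@arrayId, calibrations@pmt, sep = "."))
  cal_tab <- calibrationTable(calibrations)
  m <- measurements[!measurements$is_control, , drop = FALSE]
  idx <- match(paste(m$array_id, m$pmt), paste(cal_tab$array_id, cal_tab$pmt))
  if (anyNA(idx)) stop("measurement scan without a calibration")
  call <- callSpot(m$si, cal_tab$threshold[idx],
                   cal_tab$saturation_level[idx])
  sp <- split(seq_len(nrow(m)), m$probe_id)
  calls <- data.frame(
    probe_id = names(sp),
    n_measurements = lengths(sp),
    n_positive = vapply(sp, function(i) sum(call[i] == "present"),
                        integer(1)),
    n_flagged = vapply(sp, function(i) sum(call[i] == "saturated"),
                       integer(1)),
    mean_si = vapply(sp, function(i) {
      ok <- call[i] != "saturated"
      if (any(ok)) mean(m$si[i][ok]) else NA_real_
    }, numeric(1)),
    cv_si = vapply(sp, function(i) {
      ok <- call[i] != "saturated"
      if (sum(ok) >= 2L) sd(m$si[i][ok]) / mean(m$si[i][ok]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(probeUniverse)) {
    missing <- setdiff(probeUniverse, calls$probe_id)
    if (length(missing)) {
      warning(length(missing), " probe(s) have no spot measurements")
      calls <- rbind(calls, data.frame(
        probe_id = missing, n_measurements = 0L, n_positive = 0L,
        n_flagged = 0L, mean_si = NA_real_, cv_si = NA_real_,
        stringsAsFactors = FALSE))
    }
    calls <- calls[order(match(calls$probe_id, probeUniverse)), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  new("ProbeCallMatrix", calls = calls)
}

#' Write the per-probe call matrix as TSV
#'
#' @param pcm a [ProbeCallMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCallMatrix <- function(pcm, path) {
  write.table(probeCalls(pcm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
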