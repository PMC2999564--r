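#' Configuration of the simulated hybridization truth
#'
#' Defines the generative model of one-color array hybridization used to
#' test the calling and selection machinery end to end. Each target is
#' expressed with probability `expressedFraction` and carries one true
#' orientation; a probe whose target is expressed and whose orientation
#' matches receives `gain(pmt) * abundance * affinity * lognoise` per spot,
#' other probes receive a background draw. Probes similar to a
#' signal-bearing probe (high-identity ungapped window) additionally pick
#' up `crossHybFactor` of that probe's signal. All intensities are clipped
#' at the 16-bit scanner ceiling, which deliberately sits above the 65,000
#' saturation call level so the two concepts stay distinct.
#'
#' @param expressedFraction probability a target is expressed (default 0.5).
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters
#'   (defaults log(3000) and 1: median mRNA signal well above calibration).
#' @param backgroundMean,backgroundSd Gaussian background-subtracted SI for
#'   silent spots (defaults 40 and 25; negative draws are kept, as real
#'   background-subtracted data contain them).
#' @param gains named vector of gain factors per PMT setting, monotone in
#'   the setting (default `c("400" = 1, "500" = 2.5)`).
#' @param saturationCeiling scanner ceiling (default 65535).
#' @param crossHybFactor fraction of a similar probe's signal leaking over
#'   (default 0.05).
#' @param affinitySdlog per-probe log-normal affinity spread, drawn once
#'   per probe and reused across arrays (default 0.3).
#' @param noiseSdlog per-spot log-normal measurement noise (default 0.15;
#'   0 gives the noiseless analytic regime).
#' @param seed integer seed making the simulation reproducible.
#' @return A `TruthConfig` (classed list).
#' @export
truthConfig <- function(expressedFraction = 0.5,
                        abundanceMeanlog = log(3000), abundanceSdlog = 1,
                        backgroundMean = 40, backgroundSd = 25,
                        gains = c("400" = 1, "500" = 2.5),
                        saturationCeiling = 65535,
                        crossHybFactor = 0.05,
                        affinitySdlog = 0.3, noiseSdlog = 0.15,
                        seed = 1L) {
  stopifnot(expressedFraction >= 0, expressedFraction <= 1,
            !is.null(names(gains)),
            !is.unsorted(gains[order(as.integer(names(gains)))]))
  structure(list(expressed_fraction = expressedFraction,
                 abundance_meanlog = abundanceMeanlog,
                 abundance_sdlog = abundanceSdlog,
                 background_mean = backgroundMean,
                 background_sd = backgroundSd,
                 gains = gains, saturation_ceiling = saturationCeiling,
                 cross_hyb_factor = crossHybFactor,
                 affinity_sdlog = affinitySdlog,
                 noise_sdlog = noiseSdlog, seed = as.integer(seed)),
            class = "TruthConfig")
}

#' The spike-in control set
#'
#' Ten spike-in species at strictly increasing nominal concentrations, each
#' probed by one control probe replicated 60 times per array. Real spike
#' mixes do not publish their concentrations, so the default is a
#' documented geometric series (ratio 2 from 25 SI-equivalent units) whose
#' mean signal is strictly increasing in concentration, supporting the
#' linear-correlation-curve reading of the calibration.
#'
#' @param concentrations strictly increasing numeric vector (default
#'   `25 * 2^(0:9)`).
#' @param replicates spots per spike probe per array (default 60).
#' @return data.frame(spike_id, probe_id, concentration, replicates).
#' @export
spikeInSet <- function(concentrations = 25 * 2^(0:9), replicates = 60L) {
  stopifnot(length(concentrations) >= 3L,
            all(diff(concentrations) > 0), replicates >= 2L)
  n <- length(concentrations)
  data.frame(spike_id = sprintf("spike%02d", seq_len(n)),
             probe_id = sprintf("spike%02d", seq_len(n)),
             concentration = concentrations,
             replicates = as.integer(replicates),
             stringsAsFactors = FALSE)
}

#' Simulate a toy transcriptome
#'
#' Uniform-random sequences over {A,C,G,T} with reproducible seed, the raw
#' material for probe design and assembly fixtures.
#'
#' @param n number of targets.
#' @param lengthRange integer range of lengths (min at least 40).
#' @param seed integer seed.
#' @param source source tag (default `"synthetic"`).
#' @return A [Biostrings::DNAStringSet] named `t0001`, `t0002`, ...
#' @export
simulateTranscriptome <- function(n, lengthRange = c(100L, 400L),
                                  seed = 1L, source = "synthetic") {
  stopifnot(lengthRange[1] >= 40L, lengthRange[2] >= lengthRange[1])
  set.seed(seed)
  lens <- sample(seq.int(lengthRange[1], lengthRange[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  x <- Biostrings::DNAStringSet(setNames(seqs, sprintf("t%04d", seq_len(n))))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(source = rep(source, n))
  x
}

#' Plant a shared block between two records
#'
#' Copies a block from record `from` into record `to` (optionally with a
#' fixed number of mismatches), recording the planted positions, so
#' redundancy detectors can be tested against known truth.
#'
#' @param seqs [Biostrings::DNAStringSet] or named character vector.
#' @param from,to record indices or names.
#' @param blockLen block length (default 30).
#' @param mismatches number of bases to corrupt in the copied block.
#' @param fromStart,toStart 0-based block starts (defaults 0).
#' @return The modified collection, with attribute `planted` describing the
#'   block.
#' @export
plantSharedBlock <- function(seqs, from, to, blockLen = 30L,
                             mismatches = 0L, fromStart = 0L, toStart = 0L) {
  x <- .as_named_chr(seqs)
  blk <- substr(x[[from]], fromStart + 1L, fromStart + blockLen)
  if (mismatches > 0L) {
    pos <- seq(1L, blockLen, length.out = mismatches + 2L)
    pos <- round(pos[-c(1L, length(pos))])
    for (p in pos) {
      old <- substr(blk, p, p)
      substr(blk, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
    }
  }
  tgt <- x[[to]]
  substr(tgt, toStart + 1L, toStart + blockLen) <- blk
  x[[to]] <- tgt
  out <- Biostrings::DNAStringSet(x)
  if (is(seqs, "DNAStringSet")) S4Vectors::mcols(out) <- S4Vectors::mcols(seqs)
  attr(out, "planted") <- data.frame(
    from = names(x)[if (is.character(from)) match(from, names(x)) else from],
    to = names(x)[if (is.character(to)) match(to, names(x)) else to],
    from_start = fromStart, to_start = toStart,
    length = blockLen, mismatches = mismatches)
  out
}

#' Draw the expression truth table for a target collection
#'
#' @param targets [Biostrings::DNAStringSet] or named character vector.
#' @param config a [truthConfig()].
#' @return data.frame(target_id, expressed, orientation, abundance); the
#'   orientation column is the target's single true orientation.
#' @export
drawTruth <- function(targets, config) {
  ids <- names(.as_named_chr(targets))
  set.seed(config$seed)
  data.frame(
    target_id = ids,
    expressed = runif(length(ids)) < config$expressed_fraction,
    orientation = sample(c("sense", "antisense"), length(ids),
                         replace = TRUE),
    abundance = rlnorm(length(ids), config$abundance_meanlog,
                       config$abundance_sdlog),
    stringsAsFactors = FALSE)
}

#' Simulate one-color hybridization of a probe manifest
#'
#' Produces per-spot background-subtracted median signal intensities for
#' every feature on every array at every PMT gain, plus spike-in replicate
#' blocks and negative-control spots. Signal model per spot:
#' matched-orientation probe of an expressed target gets
#' `gain * abundance * affinity * lognoise`; anything else a Gaussian
#' background draw; cross-hybridizing probes (similar by the ungapped
#' window criterion to a signal-bearing probe) add `crossHybFactor` of that
#' signal before noise. Intensities are rounded to 2 decimals (the
#' round-trip unit of the GPR-like export) and clipped at the ceiling.
#' Deterministic given the seed.
#'
#' @param manifest probe data.frame from [designProbeSet()] /
#'   [dedupExact()].
#' @param truth data.frame from [drawTruth()].
#' @param config a [truthConfig()].
#' @param spikes a [spikeInSet()].
#' @param design optional [ArrayDesign-class]; duplicate-fill features
#'   yield extra replicate spots per probe. Without it every probe gets one
#'   spot per array/gain.
#' @param nArrays number of arrays (default 4).
#' @param pmts PMT gain settings scanned per array (default c(400, 500);
#'   must name entries of `config$gains`).
#' @param nNegControls negative-control spots per array (default 100).
#' @param similarPairs optional precomputed output of
#'   [similarSequencePairs()] on the manifest probe sequences (computed
#'   internally when `NULL`).
#' @return data.frame(probe_id, array_id, pmt, replicate, si, is_control).
#' @export
simulateHybridization <- function(manifest, truth, config, spikes,
                                  design = NULL, nArrays = 4L,
                                  pmts = c(400L, 500L),
                                  nNegControls = 100L,
                                  similarPairs = NULL) {
  stopifnot(all(as.character(pmts) %in% names(config$gains)))
  if (!is.null(design)) {
    feat <- arrayFeatures(design)
    if (!all(feat$probe_id %in% manifest$probe_id))
      stop("array design contains probe ids missing from the manifest")
    reps <- table(feat$probe_id)[manifest$probe_id]
    reps[is.na(reps)] <- 0L
    reps <- as.integer(reps)
  } else {
    reps <- rep(1L, nrow(manifest))
  }
  set.seed(config$seed + 1L)

  # per-probe base signal (abundance x affinity when orientation matches)
  tr <- truth[match(manifest$target_id, truth$target_id), , drop = FALSE]
  if (anyNA(tr$target_id)) stop("manifest targets missing from truth table")
  affinity <- rlnorm(nrow(manifest), 0, config$affinity_sdlog)
  base <- ifelse(tr$expressed & manifest$orientation == tr$orientation,
                 tr$abundance * affinity, 0)

  # cross-hybridization leak from similar signal-bearing probes
  if (is.null(similarPairs)) {
    similarPairs <- similarSequencePairs(
      setNames(manifest$seq, manifest$probe_id))
  }
  leak <- numeric(nrow(manifest))
  if (nrow(similarPairs)) {
    ia <- match(similarPairs$id_a, manifest$probe_id)
    ib <- match(similarPairs$id_b, manifest$probe_id)
    for (k in seq_len(nrow(similarPairs))) {
      leak[ia[k]] <- leak[ia[k]] + config$cross_hyb_factor * base[ib[k]]
      leak[ib[k]] <- leak[ib[k]] + config$cross_hyb_factor * base[ia[k]]
    }
  }
  signal <- base + leak

  arrays <- sprintf("A%d", seq_len(nArrays))
  out <- list()
  for (a in arrays) {
    for (pmt in pmts) {
      g <- config$gains[[as.character(pmt)]]
      # feature spots (probe replicates per the layout)
      pid <- rep(manifest$probe_id, reps)
      sig <- rep(signal, reps)
      repl <- sequence(reps)
      noise <- if (config$noise_sdlog > 0)
        rlnorm(length(pid), 0, config$noise_sdlog) else 1
      bg <- if (config$background_sd > 0)
        rnorm(length(pid), config$background_mean, config$background_sd)
      else rep(config$background_mean, length(pid))
      si <- ifelse(sig > 0, g * sig * noise, bg)
      out[[length(out) + 1L]] <- data.frame(
        probe_id = pid, array_id = a, pmt = as.integer(pmt),
        replicate = repl, si = si, is_control = FALSE,
        stringsAsFactors = FALSE)
      # spike-in replicate blocks
      spid <- rep(spikes$probe_id, spikes$replicates)
      sconc <- rep(spikes$concentration, spikes$replicates)
      snoise <- if (config$noise_sdlog > 0)
        rlnorm(length(spid), 0, config$noise_sdlog) else 1
      out[[length(out) + 1L]] <- data.frame(
        probe_id = spid, array_id = a, pmt = as.integer(pmt),
        replicate = stats::ave(seq_along(spid), spid, FUN = seq_along),
        si = g * sconc * snoise, is_control = TRUE,
        stringsAsFactors = FALSE)
      # negative controls: pure background
      if (nNegControls > 0L) {
        nbg <- if (config$background_sd > 0)
          rnorm(nNegControls, config$background_mean, config$background_sd)
        else rep(config$background_mean, nNegControls)
        out[[length(out) + 1L]] <- data.frame(
          probe_id = "negctrl", array_id = a, pmt = as.integer(pmt),
          replicate = seq_len(nNegControls), si = nbg, is_control = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res$si <- round(pmin(res$si, config$saturation_ceiling), 2)
  rownames(res) <- NULL
  res
}

#' Write spot measurements as a GPR-like tab-separated table
#'
#' Fixed column order probe_id, array_id, pmt, replicate, si, is_control;
#' SI formatted with 2 decimals (the simulator's own resolution, so the
#' round trip is lossless).
#'
#' @param measurements data.frame from [simulateHybridization()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGprLike <- function(measurements, path) {
  m <- measurements[, c("probe_id", "array_id", "pmt", "replicate", "si",
                        "is_control")]
  m$si <- sprintf("%.2f", m$si)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GPR-like spot table written by [writeGprLike()]
#'
#' @param path input path.
#' @return data.frame(probe_id, array_id, pmt, replicate, si, is_control).
#' @export
readGprLike <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  m$si <- as.numeric(m$si)
  m$is_control <- as.logical(m$is_control)
  m
}

#' Write a truth table for parameter-recovery tests
#'
#' @param truth data.frame from [drawTruth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
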