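#' Configuration of the probe selection rules
#'
#' The constants of the six-step selection: a probe is dropped when flagged
#' (saturated) in strictly more than `maxFlagFraction` of its measurements
#' (so 2 of 4, 3 of 8 or 5 of 16 flags remove it); it is called positive
#' when at least `minPositiveFraction` of its measurements are present; and
#' two probes are "highly similar" when they share an ungapped window of at
#' least `similarityMinOverlap` columns at `similarityMinIdentity` identity
#' or higher, on either strand.
#'
#' @param maxFlagFraction default 0.25, compared strictly.
#' @param minPositiveFraction default 0.75, compared inclusively.
#' @param similarityMinOverlap default 50 columns.
#' @param similarityMinIdentity default 0.95.
#' @return classed list `SelectionConfig`.
#' @export
selectionConfig <- function(maxFlagFraction = 0.25,
                            minPositiveFraction = 0.75,
                            similarityMinOverlap = 50L,
                            similarityMinIdentity = 0.95) {
  stopifnot(maxFlagFraction > 0, maxFlagFraction <= 1,
            minPositiveFraction > 0, minPositiveFraction <= 1,
            similarityMinOverlap >= 1L,
            similarityMinIdentity > 0, similarityMinIdentity <= 1)
  structure(list(max_flag_fraction = maxFlagFraction,
                 min_positive_fraction = minPositiveFraction,
                 similarity_min_overlap = as.integer(similarityMinOverlap),
                 similarity_min_identity = similarityMinIdentity),
            class = "SelectionConfig")
}

#' Step 1: remove probes flagged in more than a quarter of measurements
#'
#' A probe is removed iff `n_flagged / n_measurements` strictly exceeds the
#' configured fraction: at the 0.25 default, 2/4, 3/8 and 5/16 are the
#' smallest removing flag counts, while 1/4, 2/8 and 4/16 are retained.
#'
#' @param pcm a [ProbeCallMatrix-class].
#' @param cfg a [selectionConfig()].
#' @return list(retained = [ProbeCallMatrix-class], removed = data.frame
#'   of dropped rows with a reason column).
#' @export
filterFlagged <- function(pcm, cfg = selectionConfig()) {
  d <- probeCalls(pcm)
  if (any(d$n_measurements < 1L))
    stop("every probe must have at least one measurement")
  drop <- d$n_flagged / d$n_measurements > cfg$max_flag_fraction
  removed <- d[drop, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- sprintf("flagged %d/%d > %.2f", removed$n_flagged,
                              removed$n_measurements, cfg$max_flag_fraction)
  list(retained = new("ProbeCallMatrix", calls = d[!drop, , drop = FALSE]),
       removed = removed)
}

#' Call positive probes
#'
#' Positive iff at least the configured fraction of measurements are
#' present: 6 of 8 is positive at the 0.75 default, 5 of 8 is not.
#'
#' @param pcm a [ProbeCallMatrix-class] (normally [filterFlagged()]
#'   survivors).
#' @param cfg a [selectionConfig()].
#' @return data.frame of positive probes (call-matrix columns).
#' @export
callPositive <- function(pcm, cfg = selectionConfig()) {
  d <- probeCalls(pcm)
  d[d$n_positive / d$n_measurements >= cfg$min_positive_fraction - 1e-12, ,
    drop = FALSE]
}

#' Steps 2-6: reduce positive probes to one validated probe per target
#'
#' Applies, in order: (2) within-orientation removal of probes with
#' identical sequences; (3) within-orientation removal of redundant targets
#' (identical target sequence) and reduction to a single probe per target;
#' (4) the same removals across orientations (identical probe sequences and
#' targets validated in both orientations); (5) removal of highly similar
#' probes, judged by the ungapped window criterion on probe sequences (95%
#' identity over 50 or more consecutive columns, either strand, by
#' default). At every conflict the probe with the higher mean SI survives
#' (step 6, applied as the universal tie-break inside steps 2-5; residual
#' ties go to the lexicographically smaller probe id). Every removal is
#' logged with its step.
#'
#' Redundant targets are recognized by exact sequence identity only;
#' targets that merely overlap are deliberately left in place, a documented
#' limitation of sequence-level deduplication without re-assembly.
#'
#' @param positives data.frame with columns probe_id, target_id,
#'   orientation, seq, target_seq, mean_si, cv_si (from [callPositive()]
#'   joined with the probe manifest and target sequences; see
#'   [joinProbeData()]).
#' @param cfg a [selectionConfig()].
#' @return A [ValidatedProbeSet-class].
#' @export
selectUnique <- function(positives, cfg = selectionConfig()) {
  need <- c("probe_id", "target_id", "orientation", "seq", "target_seq",
            "mean_si")
  miss <- setdiff(need, names(positives))
  if (length(miss))
    stop("positives lack required column(s): ", paste(miss, collapse = ", "))
  if (anyNA(positives$seq) || anyNA(positives$mean_si))
    stop("missing probe sequence or mean SI for a positive probe")
  if (!"cv_si" %in% names(positives)) positives$cv_si <- NA_real_
  d <- positives
  log <- data.frame(probe_id = character(), step = integer(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(ids, step, reason) {
    log <<- rbind(log, data.frame(probe_id = ids, step = step,
                                  reason = reason,
                                  stringsAsFactors = FALSE))
  }
  # deterministic survivor of a conflict set: highest mean SI, then lex id
  survivor <- function(idx) {
    idx[order(-d$mean_si[idx], d$probe_id[idx])][1L]
  }
  drop_groups <- function(keys, step, reason) {
    for (g in split(seq_len(nrow(d)), keys)) {
      if (length(g) < 2L) next
      keep <- survivor(g)
      note(d$probe_id[setdiff(g, keep)], step, reason)
    }
    dropped <- log$probe_id[log$step == step]
    d <<- d[!(d$probe_id %in% dropped), , drop = FALSE]
  }

  # step 2: redundant probe sequences within each orientation
  drop_groups(paste(d$orientation, d$seq), 2L,
              "redundant probe sequence within orientation")

  # step 3: redundant targets within each orientation -- identical target
  # sequences collapse to one target, and each target keeps one probe
  for (g in split(seq_len(nrow(d)), paste(d$orientation, d$target_seq))) {
    tids <- unique(d$target_id[g])
    if (length(tids) < 2L) next
    keep_target <- d$target_id[survivor(g)]
    loser <- g[d$target_id[g] != keep_target]
    note(d$probe_id[loser], 3L, "redundant target sequence within orientation")
  }
  d <- d[!(d$probe_id %in% log$probe_id), , drop = FALSE]
  drop_groups(paste(d$orientation, d$target_id), 3L,
              "additional probe on the same target within orientation")

  # step 4: redundancy across orientations (probe sequences and targets)
  drop_groups(d$seq, 4L, "redundant probe sequence across orientations")
  drop_groups(d$target_id, 4L, "target validated in both orientations")

  # step 5: highly similar probes (cross-hybridization risk)
  if (nrow(d) >= 2L) {
    pairs <- similarSequencePairs(
      setNames(d$seq, d$probe_id),
      minOverlap = cfg$similarity_min_overlap,
      minIdentity = cfg$similarity_min_identity)
    if (nrow(pairs)) {
      pairs <- unique(pairs[, c("id_a", "id_b")])
      pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
      alive <- setNames(rep(TRUE, nrow(d)), d$probe_id)
      for (k in seq_len(nrow(pairs))) {
        a <- pairs$id_a[k]; b <- pairs$id_b[k]
        if (!alive[a] || !alive[b]) next
        ia <- match(a, d$probe_id); ib <- match(b, d$probe_id)
        loser <- if (d$mean_si[ia] < d$mean_si[ib]) a
                 else if (d$mean_si[ib] < d$mean_si[ia]) b
                 else max(a, b)
        alive[loser] <- FALSE
        note(loser, 5L, sprintf("highly similar to probe %s",
                                if (loser == a) b else a))
      }
      d <- d[alive[d$probe_id], , drop = FALSE]
    }
  }

  entries <- data.frame(
    probe_id = d$probe_id, target_id = d$target_id,
    orientation = d$orientation, probe_length = nchar(d$seq),
    seq = d$seq, target_length = nchar(d$target_seq),
    mean_si = d$mean_si, cv_si = d$cv_si,
    stringsAsFactors = FALSE, row.names = NULL)
  new("ValidatedProbeSet", entries = entries, log = log,
      config = unclass(cfg))
}

#' Join call results with probe and target sequences
#'
#' Prepares the input of [selectUnique()] from a call matrix (or the
#' positive subset of one), the probe manifest and the target collection.
#' Errors when a probe lacks its sequence or target.
#'
#' @param calls data.frame of call-matrix rows (e.g. from
#'   [callPositive()]).
#' @param manifest probe data.frame from [designProbeSet()].
#' @param targets [Biostrings::DNAStringSet] or named character vector.
#' @return data.frame ready for [selectUnique()].
#' @export
joinProbeData <- function(calls, manifest, targets) {
  tg <- .as_named_chr(targets)
  i <- match(calls$probe_id, manifest$probe_id)
  if (anyNA(i)) stop("call matrix contains probes missing from the manifest")
  out <- cbind(calls,
               manifest[i, c("target_id", "orientation", "seq"),
                        drop = FALSE])
  j <- match(out$target_id, names(tg))
  if (anyNA(j)) stop("manifest references targets missing from the collection")
  out$target_seq <- unname(tg[j])
  rownames(out) <- NULL
  out
}

#' Summarize a validated probe set
#'
#' Counts by orientation and probe length, orientation percentages among
#' 60-mers (1 decimal), the total targeted bases, and, given a genome size,
#' the fraction of the genome the targeted transcripts cover.
#'
#' @param x a [ValidatedProbeSet-class].
#' @param genomeSizeMb optional genome size in Mb for the coverage figure.
#' @return list(n_total, counts, sense_percent, targeted_bases,
#'   targeted_mb, coverage_percent).
#' @export
summarizeProbeSet <- function(x, genomeSizeMb = NULL) {
  e <- validatedProbes(x)
  counts <- as.data.frame(table(orientation = e$orientation,
                                probe_length = e$probe_length),
                          responseName = "n")
  s60 <- sum(e$orientation == "sense" & e$probe_length == 60L)
  a60 <- sum(e$orientation == "antisense" & e$probe_length == 60L)
  targeted <- sum(e$target_length)
  list(n_total = nrow(e), counts = counts,
       sense_percent = orientationSharePercent(s60, a60),
       targeted_bases = targeted,
       targeted_mb = targeted / 1e6,
       coverage_percent = if (is.null(genomeSizeMb)) NA_real_
                          else coveragePercent(targeted / 1e6, genomeSizeMb))
}

#' Orientation share among 60-mer probes, to one decimal
#'
#' @param nSense,nAntisense probe counts.
#' @return percentage of sense probes, rounded to 1 decimal.
#' @examples
#' orientationSharePercent(33740, 28133)  # 54.5
#' @export
orientationSharePercent <- function(nSense, nAntisense) {
  if (nSense + nAntisense == 0) return(NA_real_)
  round(100 * nSense / (nSense + nAntisense), 1)
}

#' Genome coverage percentage, to one decimal
#'
#' @param targetedMb total targeted transcript length in Mb.
#' @param genomeMb genome size in Mb.
#' @return percentage, rounded to 1 decimal.
#' @examples
#' coveragePercent(10.4, 700)  # 1.5
#' @export
coveragePercent <- function(targetedMb, genomeMb) {
  round(100 * targetedMb / genomeMb, 1)
}

#' Total probes across validated categories
#'
#' @param counts named integer vector of per-category validated probe
#'   counts (e.g. sense/antisense 60-mers and 40-mers).
#' @return integer total.
#' @examples
#' probeSetTotal(c(sense60 = 33740, antisense60 = 28133, mer40 = 1668))
#' @export
probeSetTotal <- function(counts) {
  as.integer(sum(counts))
}

#' Write a validated probe set as TSV + FASTA + provenance log
#'
#' @param x a [ValidatedProbeSet-class].
#' @param prefix path prefix; writes `<prefix>_validated.tsv`,
#'   `<prefix>_validated.fasta` and `<prefix>_provenance.tsv`.
#' @return character vector of paths, invisibly.
#' @export
writeValidatedSet <- function(x, prefix) {
  e <- validatedProbes(x)
  tsv <- paste0(prefix, "_validated.tsv")
  fa <- paste0(prefix, "_validated.fasta")
  lg <- paste0(prefix, "_provenance.tsv")
  write.table(e[, setdiff(names(e), "seq")], tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeFastaRecords(setNames(e$seq, e$probe_id), fa)
  write.table(selectionLog(x), lg, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(tsv, fa, lg))
}
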