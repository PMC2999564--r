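#' Design rule for a target sequence
#'
#' How many probes of which length a target receives, and by which method:
#' `best_probe` picks the single highest-scoring window, `best_distribution`
#' spreads several probes across the target. Multi-probe rules always use
#' `best_distribution`; 40-mer probes are always single.
#'
#' @param probeLength 40 or 60.
#' @param probesPerTarget 1, 2 or 4.
#' @param method `"best_probe"` or `"best_distribution"`.
#' @return A `DesignRule` (classed list).
#' @export
designRule <- function(probeLength, probesPerTarget, method) {
  probeLength <- as.integer(probeLength)
  probesPerTarget <- as.integer(probesPerTarget)
  stopifnot(probeLength %in% c(40L, 60L),
            probesPerTarget %in% c(1L, 2L, 4L),
            method %in% c("best_probe", "best_distribution"))
  if (probesPerTarget >= 2L && method != "best_distribution")
    stop("multi-probe rules must use the best_distribution method")
  if (probeLength == 40L && probesPerTarget != 1L)
    stop("40-mer probes are single-probe only")
  structure(list(probe_length = probeLength,
                 probes_per_target = probesPerTarget,
                 method = method, rejected = FALSE),
            class = "DesignRule")
}

#' Classify a target by length into its design rule
#'
#' Length classes: below 40 bases the target is rejected (no probe class
#' exists); 40-59 gets one 40-mer (best probe); 60-150 one 60-mer (best
#' probe); 151-300 two 60-mers (best distribution); above 300 four 60-mers.
#' The class boundaries are strict on "longer than": a 150-base target gets
#' a single probe, a 300-base target two. A `sourceOverride` rule (e.g. two
#' probes for every SSH-library target regardless of length) wins when
#' provided.
#'
#' @param length target length in bases.
#' @param sourceOverride optional [designRule()] that overrides the length
#'   classification.
#' @return A `DesignRule`; rejected targets return a rule with
#'   `rejected = TRUE`.
#' @export
classifyTarget <- function(length, sourceOverride = NULL) {
  stopifnot(length >= 1)
  if (!is.null(sourceOverride)) {
    stopifnot(inherits(sourceOverride, "DesignRule"))
    return(sourceOverride)
  }
  if (length < 40) {
    return(structure(list(probe_length = NA_integer_,
                          probes_per_target = 0L,
                          method = "rejected", rejected = TRUE),
                     class = "DesignRule"))
  }
  if (length < 60) return(designRule(40L, 1L, "best_probe"))
  if (length <= 150) return(designRule(60L, 1L, "best_probe"))
  if (length <= 300) return(designRule(60L, 2L, "best_distribution"))
  designRule(60L, 4L, "best_distribution")
}

#' Score one candidate probe window
#'
#' The deterministic design criterion:
#' `-|GC - 0.5| - 0.05 * max(longest homopolymer - 4, 0) - 0.02 *
#' max(longest self-complementary stretch - 8, 0)`, higher is better; a
#' window with more than 10% N is ineligible and scores `-Inf`. The
#' self-complementary stretch is the longest substring whose reverse
#' complement also occurs in the window (a hairpin/self-dimer proxy). The
#' exact functional form is a package-defined stand-in for the proprietary
#' criterion of commercial design tools; what the pipeline relies on is
#' that it is deterministic and total, so probe placement is reproducible.
#'
#' @param window character scalar of length 40 or 60.
#' @return numeric score (0 is the best attainable).
#' @examples
#' scoreWindow(strrep("ACGT", 15))   # 0: balanced, no runs, no hairpin
#' scoreWindow(strrep("A", 60))      # -3.3
#' @export
scoreWindow <- function(window) {
  stopifnot(nchar(window) %in% c(40L, 60L))
  as.numeric(score_windows_cpp(window, nchar(window))[1L])
}

#' Design probes for one target
#'
#' `best_probe` returns the single highest-scoring window (ties to the
#' smallest start). `best_distribution` with k probes partitions the target
#' into k equal-length segments and picks the highest-scoring window fully
#' contained in each; when a segment is shorter than the probe length the
#' window may extend into neighboring segments, and chosen windows are
#' always pairwise distinct. Antisense probes are windows of the reverse
#' complement, with starts on the reverse-complement coordinate.
#'
#' @param target named character scalar (the name is the target id) or a
#'   length-1 [Biostrings::DNAStringSet].
#' @param rule a [designRule()]; default classifies by length.
#' @param orientation `"sense"`, `"antisense"`, or `"both"`.
#' @param group probe-group label recorded with each probe (default
#'   `"default"`).
#' @return data.frame(probe_id, target_id, orientation, start, length, seq,
#'   group); zero rows (with a warning) when the target is shorter than the
#'   probe length or rejected.
#' @export
designProbes <- function(target, rule = NULL, orientation = "both",
                         group = "default") {
  tg <- .as_named_chr(target)
  stopifnot(length(tg) == 1L)
  id <- names(tg); seq <- tg[[1L]]
  if (is.null(rule)) rule <- classifyTarget(nchar(seq))
  empty <- data.frame(probe_id = character(), target_id = character(),
                      orientation = character(), start = integer(),
                      length = integer(), seq = character(),
                      group = character(), stringsAsFactors = FALSE)
  if (isTRUE(rule$rejected)) {
    warning("target '", id, "' rejected: below the smallest designable class")
    return(empty)
  }
  if (nchar(seq) < rule$probe_length) {
    warning("target '", id, "' shorter than the probe length; no probes")
    return(empty)
  }
  ors <- if (orientation == "both") c("sense", "antisense") else orientation
  stopifnot(all(ors %in% c("sense", "antisense")))
  out <- lapply(ors, function(o) {
    s <- if (o == "sense") seq else revComp(seq)
    starts <- .place_windows(s, rule)
    if (!length(starts)) return(empty)
    data.frame(probe_id = sprintf("%s|%s|%d", id, o, starts),
               target_id = id, orientation = o, start = starts,
               length = rule$probe_length,
               seq = substring(s, starts + 1L, starts + rule$probe_length),
               group = group, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# 0-based window starts chosen by the rule on the oriented sequence
.place_windows <- function(s, rule) {
  L <- nchar(s); plen <- rule$probe_length
  scores <- as.numeric(score_windows_cpp(s, plen))
  if (!any(is.finite(scores))) return(integer(0))
  if (rule$method == "best_probe" || rule$probes_per_target == 1L) {
    return(which.max(scores) - 1L)  # which.max takes the first maximum
  }
  k <- rule$probes_per_target
  bounds <- floor(L * (0:k) / k)
  chosen <- integer(0)
  for (i in seq_len(k)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    cand <- seq.int(lo, hi - plen)        # fully contained, 0-based
    cand <- cand[cand >= 0L & cand + plen <= L]
    if (!length(cand)) {                  # segment shorter than the probe:
      cand <- seq.int(max(0L, hi - plen), min(lo, L - plen))
    }
    cand <- setdiff(cand, chosen)
    if (!length(cand)) next
    sc <- scores[cand + 1L]
    if (!any(is.finite(sc))) next
    chosen <- c(chosen, cand[which.max(sc)])
  }
  sort(chosen)
}

#' Design probes for a whole target collection
#'
#' Classifies each target by [classifyTarget()] (or a per-source override)
#' and concatenates the per-target designs. The probe group defaults to the
#' target's source tag, defining the scope of within-group deduplication.
#'
#' @param targets [Biostrings::DNAStringSet] or named character vector.
#' @param orientation `"sense"`, `"antisense"`, or `"both"`.
#' @param overrides optional named list mapping a source tag to a
#'   [designRule()] override (e.g. `list(sanger_ssh = designRule(60, 2,
#'   "best_distribution"))`).
#' @return data.frame as in [designProbes()].
#' @export
designProbeSet <- function(targets, orientation = "both", overrides = list()) {
  tg <- .as_named_chr(targets)
  src <- .source_of(targets, length(tg))
  out <- vector("list", length(tg))
  for (i in seq_along(tg)) {
    ov <- overrides[[src[i]]]
    rule <- classifyTarget(nchar(tg[[i]]), sourceOverride = ov)
    if (isTRUE(rule$rejected)) next
    out[[i]] <- designProbes(setNames(tg[i], names(tg)[i]), rule,
                             orientation = orientation, group = src[i])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(probe_id = character(), target_id = character(),
                      orientation = character(), start = integer(),
                      length = integer(), seq = character(),
                      group = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Remove probes with identical sequences
#'
#' Keeps exactly one representative per distinct probe sequence: the first
#' in (group order, then target id) order, so earlier probe groups have
#' priority, mirroring group-priority exclusion of probes already covered
#' by another group. The removed probes are attached as an attribute and
#' the removed count reported.
#'
#' @param probes data.frame from [designProbeSet()].
#' @param groupOrder optional character vector giving group priority;
#'   defaults to order of first appearance.
#' @return The deduplicated data.frame, with attributes `removed`
#'   (data.frame of dropped rows) and `n_removed`.
#' @export
dedupExact <- function(probes, groupOrder = unique(probes$group)) {
  if (!nrow(probes)) {
    attr(probes, "removed") <- probes
    attr(probes, "n_removed") <- 0L
    return(probes)
  }
  o <- order(match(probes$group, groupOrder), probes$target_id)
  p <- probes[o, , drop = FALSE]
  dup <- duplicated(p$seq)
  out <- p[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- p[dup, , drop = FALSE]
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Lay probes out on a fixed-format array
#'
#' The feature capacity is `totalSpots - controlSpots` (the 244K format:
#' 243,504 spots, 2,105 controls, hence 241,399 features). Every unique
#' probe is placed once; remaining capacity is filled by cycling through
#' the probes in input order as duplicate features.
#'
#' @param probes data.frame with at least a `probe_id` column (unique ids).
#' @param totalSpots,controlSpots array format constants (defaults:
#'   243504 and 2105).
#' @return An [ArrayDesign-class].
#' @export
buildLayout <- function(probes, totalSpots = 243504L, controlSpots = 2105L) {
  ids <- probes$probe_id
  if (anyDuplicated(ids)) stop("probe ids must be unique; run dedupExact()")
  capacity <- as.integer(totalSpots) - as.integer(controlSpots)
  n <- length(ids)
  if (n > capacity) {
    stop("layout overflow: ", n, " unique probes exceed the feature ",
         "capacity of ", capacity, " by ", n - capacity)
  }
  fill <- capacity - n
  fill_ids <- if (fill > 0L) ids[((seq_len(fill) - 1L) %% n) + 1L]
              else character(0)
  feat <- data.frame(probe_id = c(ids, fill_ids), stringsAsFactors = FALSE)
  # replicate_index: 1 for the unique placement, 2, 3, ... for fills
  feat$replicate_index <- as.integer(
    stats::ave(seq_along(feat$probe_id), feat$probe_id, FUN = seq_along))
  new("ArrayDesign", totalSpots = as.integer(totalSpots),
      controlSpots = as.integer(controlSpots), nUnique = n,
      nDuplicateFill = as.integer(fill), features = feat)
}

#' Write a probe manifest and layout as TSV + FASTA
#'
#' @param probes data.frame from [designProbeSet()].
#' @param design optional [ArrayDesign-class] for the layout file.
#' @param prefix path prefix; writes `<prefix>_probes.fasta`,
#'   `<prefix>_manifest.tsv` and (with a design) `<prefix>_layout.tsv`.
#' @return character vector of paths written, invisibly.
#' @export
writeProbeManifest <- function(probes, design = NULL, prefix) {
  fa <- paste0(prefix, "_probes.fasta")
  tsv <- paste0(prefix, "_manifest.tsv")
  writeFastaRecords(setNames(probes$seq, probes$probe_id), fa)
  write.table(probes[, c("probe_id", "target_id", "orientation", "start",
                         "length", "group")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(fa, tsv)
  if (!is.null(design)) {
    lay <- paste0(prefix, "_layout.tsv")
    write.table(arrayFeatures(design), lay, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, lay)
  }
  invisible(paths)
}
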