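#' Assembly completeness test
#'
#' Measures within-assembly redundancy, the signature of an assembler that
#' has not exhausted its merging opportunities: every sequence is aligned
#' against all others in the same assembly (self-hits excluded) and the
#' report tallies (i) significant hits, counted as hits (a qualifying
#' (query, subject, strand) alignment each), and (ii) sequences carrying an
#' ungapped overlap of at least `minOverlap` columns with any other
#' sequence, at 100% identity and at strictly more than 95% identity. The
#' identity categories are nested (a perfect overlap also counts in the
#' >95% column) and tally sequences, not hits.
#'
#' @param assembly a [Biostrings::DNAStringSet] (a `source` metadata column,
#'   e.g. contig/singleton, drives the per-class breakdown) or named
#'   character vector.
#' @param eThreshold significance threshold on the E-value (default 1e-5).
#' @param minOverlap minimum ungapped overlap in columns (default 25).
#' @param nearIdentity the near-identity fraction, compared strictly
#'   (default 0.95).
#' @param params,wordSize alignment scoring and seed length
#'   (see [localAlign()]).
#' @return A [CompletenessReport-class].
#' @export
completenessTest <- function(assembly, eThreshold = 1e-5, minOverlap = 25L,
                             nearIdentity = 0.95,
                             params = scoringParams(), wordSize = 11L) {
  seqs <- .as_named_chr(assembly)
  src <- .source_of(assembly, length(seqs))
  classes <- unique(src)
  if (length(seqs) < 2L) {
    warning("fewer than 2 sequences: completeness report is all zeros")
    counts <- data.frame(class = c(classes, "Total"),
                         n_sequences = c(as.integer(table(src)[classes]),
                                         length(seqs)),
                         n_significant_hits = 0L, n_identical = 0L,
                         n_near_identical = 0L, stringsAsFactors = FALSE)
    return(new("CompletenessReport", counts = counts,
               eThreshold = eThreshold, minOverlap = as.integer(minOverlap)))
  }
  ka <- solveLambda(params)
  minScore <- .min_score_for_e(ka, eThreshold,
                               max(nchar(seqs)), max(nchar(seqs)))
  hits <- localAlign(seqs, seqs, params = params, minScore = minScore,
                     wordSize = wordSize, sameSet = TRUE)
  hits <- hits[hits$evalue <= eThreshold, , drop = FALSE]

  ident <- similarSequencePairs(seqs, minOverlap = minOverlap,
                                minIdentity = 1.0, strict = FALSE)
  near <- similarSequencePairs(seqs, minOverlap = minOverlap,
                               minIdentity = nearIdentity, strict = TRUE)
  in_ident <- unique(c(ident$id_a, ident$id_b))
  in_near <- unique(c(near$id_a, near$id_b))

  per_class <- lapply(classes, function(cl) {
    ids <- names(seqs)[src == cl]
    data.frame(class = cl, n_sequences = length(ids),
               n_significant_hits = sum(hits$query_id %in% ids),
               n_identical = sum(ids %in% in_ident),
               n_near_identical = sum(ids %in% in_near),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, per_class)
  counts <- rbind(counts, data.frame(
    class = "Total", n_sequences = length(seqs),
    n_significant_hits = nrow(hits),
    n_identical = length(in_ident), n_near_identical = length(in_near),
    stringsAsFactors = FALSE))
  new("CompletenessReport", counts = counts, eThreshold = eThreshold,
      minOverlap = as.integer(minOverlap))
}

#' Assembly correctness test
#'
#' Aligns each assembly sequence against one or more reference EST sets
#' (typically longer, high-confidence Sanger sequences of the same species
#' and of congeners). For each assembly sequence and reference set, only the
#' single most significant hit is considered (lowest E-value; ties broken by
#' higher score, then lexicographic subject id). The sequence counts toward
#' full-length identity iff the shorter of query and subject is at least
#' `minFullLength` bases and the best hit's identities divided by that
#' shorter length reach the per-set identity threshold.
#'
#' @param assembly a [Biostrings::DNAStringSet] or named character vector.
#' @param refs named list of reference sets (each a DNAStringSet or named
#'   character vector), e.g. `list(EF = ..., EA_LS = ...)`.
#' @param identityThresholds named numeric vector of per-set identity
#'   fractions (defaults: 0.90 for every set; the convention is 0.90 for
#'   same-species references and 0.80 for congeners).
#' @param minFullLength minimum "full length" in bases (default 100).
#' @param eThreshold significance threshold (default 1e-5).
#' @param params,wordSize see [localAlign()].
#' @return A [CorrectnessReport-class].
#' @export
correctnessTest <- function(assembly, refs, identityThresholds = NULL,
                            minFullLength = 100L, eThreshold = 1e-5,
                            params = scoringParams(), wordSize = 11L) {
  stopifnot(is.list(refs), length(refs) >= 1L, !is.null(names(refs)))
  seqs <- .as_named_chr(assembly)
  src <- .source_of(assembly, length(seqs))
  classes <- unique(src)
  if (is.null(identityThresholds))
    identityThresholds <- setNames(rep(0.90, length(refs)), names(refs))
  ka <- solveLambda(params)

  rows <- list()
  for (rs in names(refs)) {
    ref <- .as_named_chr(refs[[rs]])
    thr <- identityThresholds[[rs]]
    minScore <- .min_score_for_e(ka, eThreshold,
                                 max(nchar(seqs)), max(nchar(ref)))
    hits <- localAlign(seqs, ref, params = params, minScore = minScore,
                       wordSize = wordSize)
    best <- .best_hit_per_query(hits)
    sig <- best[best$evalue <= eThreshold, , drop = FALSE]
    if (nrow(sig)) {
      shorter <- pmin(nchar(seqs)[sig$query_id],
                      nchar(ref)[sig$subject_id])
      full <- shorter >= minFullLength &
        sig$identities / shorter >= thr - 1e-12
    } else {
      full <- logical(0)
    }
    for (cl in c(classes, "Total")) {
      ids <- if (cl == "Total") names(seqs) else names(seqs)[src == cl]
      sel <- sig$query_id %in% ids
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, ref_set = rs, n_sequences = length(ids),
        n_significant = sum(sel), n_full_length = sum(full & sel),
        identity_threshold = thr, stringsAsFactors = FALSE)
    }
  }
  new("CorrectnessReport", counts = do.call(rbind, rows),
      minFullLength = as.integer(minFullLength), eThreshold = eThreshold)
}

# smallest integer score whose E-value is at or below the threshold for the
# largest search space in play (hits below it can never be significant)
.min_score_for_e <- function(ka, eThreshold, m, n) {
  s <- ceiling(log(ka@K * m * n / eThreshold) / ka@lambda)
  max(1L, as.integer(s))
}

.best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, hits$evalue, -hits$score, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

.source_of <- function(x, n) {
  if (is(x, "DNAStringSet") && !is.null(S4Vectors::mcols(x)$source))
    as.character(S4Vectors::mcols(x)$source)
  else rep("sequence", n)
}

#' Write a QC report as tab-separated text
#'
#' One row per (class, category), mirroring the completeness/correctness
#' table layout.
#'
#' @param report a [CompletenessReport-class] or [CorrectnessReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQcReport <- function(report, path) {
  write.table(reportCounts(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
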