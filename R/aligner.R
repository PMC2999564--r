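#' Construct local-alignment scoring parameters
#'
#' Defaults are BLASTN-like: +1 match, -2 mismatch, -5 gap open, -2 gap
#' extend (a gap of length g costs `gapOpen + g * gapExtend`), with uniform
#' background composition. Validity requires a negative expected per-column
#' score, the condition under which Karlin-Altschul statistics apply.
#'
#' @param match,mismatch,gapOpen,gapExtend integer scores; penalties
#'   negative.
#' @param composition background frequencies of A, C, G, T.
#' @return A [ScoringParams-class] object.
#' @export
scoringParams <- function(match = 1L, mismatch = -2L, gapOpen = -5L,
                          gapExtend = -2L, composition = rep(0.25, 4)) {
  new("ScoringParams", match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend), composition = composition)
}

#' Solve the ungapped Karlin-Altschul parameters
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` for the match/mismatch scoring
#' system under the background composition. `K` is computed by the standard
#' lattice series
#' `K = delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))`
#' where `delta` is the score span (gcd of attainable scores), `H` the
#' relative entropy `lambda * E[s exp(lambda s)]`, and
#' `sigma = sum_k (1/k) (P(S_k >= 0) + E[exp(lambda S_k); S_k < 0])` over
#' partial sums `S_k` of the per-column score; the series is truncated at 50
#' terms or when a term falls below 1e-9.
#'
#' @param params a [ScoringParams-class] object (gap penalties are ignored:
#'   the statistics are for the ungapped regime).
#' @return A [KarlinAltschulParams-class] object.
#' @examples
#' solveLambda(scoringParams(match = 1, mismatch = -1))  # lambda = ln 3
#' @export
solveLambda <- function(params) {
  stopifnot(is(params, "ScoringParams"))
  p <- params@composition
  pm <- sum(p^2)
  scores <- c(params@match, params@mismatch)
  probs <- c(pm, 1 - pm)
  es <- sum(probs * scores)
  if (es >= 0) stop("expected per-column score is non-negative; ",
                    "Karlin-Altschul statistics undefined")
  f <- function(l) sum(probs * exp(l * scores)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  H <- lambda * sum(probs * scores * exp(lambda * scores))
  delta <- .gcd2(abs(scores[1]), abs(scores[2]))

  # sigma series over the lattice distribution of partial sums S_k
  lo <- min(scores); hi_s <- max(scores)
  # dist: named numeric over integer support
  support <- scores
  dist <- setNames(probs, as.character(scores))
  sigma <- 0
  d <- dist
  for (k in 1:50) {
    sv <- as.integer(names(d))
    neg <- sv < 0
    term <- sum(d[!neg]) + sum(d[neg] * exp(lambda * sv[neg]))
    sigma <- sigma + term / k
    if (term / k < 1e-9) break
    if (k < 50) d <- .convolve_lattice(d, dist)
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  new("KarlinAltschulParams", lambda = lambda, K = K, H = H)
}

.gcd2 <- function(a, b) {
  while (b) { t <- b; b <- a %% b; a <- t }
  a
}

.convolve_lattice <- function(d1, d2) {
  s1 <- as.integer(names(d1)); s2 <- as.integer(names(d2))
  lo <- min(s1) + min(s2); hi <- max(s1) + max(s2)
  out <- numeric(hi - lo + 1L)
  for (i in seq_along(s1)) {
    idx <- s1[i] + s2 - lo + 1L
    out[idx] <- out[idx] + d1[i] * d2
  }
  keep <- out > 0
  setNames(out[keep], as.character(seq(lo, hi)[keep]))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)` with the raw search space `m * n`
#' (no edge-effect length adjustment: the sequences handled here are short
#' and the tests only threshold at E <= 1e-5, so raw search space keeps
#' counts bit-reproducible).
#'
#' @param score integer alignment score(s).
#' @param m,n lengths of the query and subject.
#' @param ka a [KarlinAltschulParams-class] object.
#' @return numeric E-value(s).
#' @export
evalueKA <- function(score, m, n, ka) {
  stopifnot(is(ka, "KarlinAltschulParams"), m >= 1, n >= 1)
  ka@K * m * n * exp(-ka@lambda * score)
}

#' Local pairwise alignment of EST sequences
#'
#' A BLASTN-like search standing in for the paper-and-pencil role BLASTN
#' plays in the assembly quality tests: exact-word seeding (both strands)
#' selects candidate query/subject/strand triples; each seeded triple is
#' resolved by a full affine-gap Smith-Waterman with traceback, and the best
#' local alignment is reported when it reaches `minScore`. E-values use the
#' ungapped Karlin-Altschul parameters for the scoring system and the raw
#' `m * n` search space of the pair. Among equal-scoring alignments the one
#' with the smallest `(q_start, s_start)` is kept. N never counts as an
#' identity and scores as a mismatch.
#'
#' @param query,subject [Biostrings::DNAStringSet] objects or named
#'   character vectors.
#' @param params a [ScoringParams-class]; default [scoringParams()].
#' @param minScore minimum reported score (default 20).
#' @param wordSize exact-match seed length (default 11; use 3 with
#'   `minScore >= 3` for provably lossless seeding of short sequences under
#'   +1/-2 scoring).
#' @param sameSet logical; if `TRUE`, self-comparisons (same id) are
#'   skipped, as in an all-vs-all within-assembly search.
#' @return data.frame with columns query_id, subject_id, strand, q_start,
#'   q_end, s_start, s_end (0-based half-open on the forward strands),
#'   aligned_cols, identities, mismatches, gaps, score, evalue; one row per
#'   seeded (query, subject, strand) triple reaching `minScore`.
#' @export
localAlign <- function(query, subject, params = scoringParams(),
                       minScore = 20L, wordSize = 11L, sameSet = FALSE) {
  q <- .as_named_chr(query); s <- .as_named_chr(subject)
  if (any(nchar(q) == 0L) || any(nchar(s) == 0L))
    stop("empty sequences cannot be aligned")
  ka <- solveLambda(params)
  cand <- seed_pairs_cpp(unname(q), unname(s), as.integer(wordSize),
                         FALSE)
  rows <- vector("list", nrow(cand))
  nkeep <- 0L
  for (r in seq_len(nrow(cand))) {
    qi <- cand[r, 1L]; si <- cand[r, 2L]; st <- cand[r, 3L]
    if (sameSet && names(q)[qi] == names(s)[si]) next
    subj <- if (st == 1L) s[[si]] else revComp(s[[si]])
    hit <- sw_best_hit_cpp(q[[qi]], subj, params@match, params@mismatch,
                           params@gapOpen, params@gapExtend)
    if (!isTRUE(hit$found) || hit$score < minScore) next
    Ls <- nchar(s[[si]])
    if (st == 1L) {
      ss <- hit$s_start; se <- hit$s_end
    } else {
      ss <- Ls - hit$s_end; se <- Ls - hit$s_start
    }
    nkeep <- nkeep + 1L
    rows[[nkeep]] <- data.frame(
      query_id = names(q)[qi], subject_id = names(s)[si],
      strand = if (st == 1L) "+" else "-",
      q_start = hit$q_start, q_end = hit$q_end,
      s_start = ss, s_end = se,
      aligned_cols = hit$aligned_cols, identities = hit$identities,
      mismatches = hit$mismatches, gaps = hit$gaps,
      score = hit$score,
      evalue = evalueKA(hit$score, nchar(q[[qi]]), Ls, ka),
      stringsAsFactors = FALSE)
  }
  if (nkeep == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      strand = character(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), aligned_cols = integer(),
                      identities = integer(), mismatches = integer(),
                      gaps = integer(), score = integer(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[seq_len(nkeep)])
  out[order(out$query_id, out$evalue, -out$score, out$subject_id), ,
      drop = FALSE]
}

.as_named_chr <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  setNames(as.character(x), names(x))
}

#' Write alignment hits as a 12-column tab-separated report
#'
#' BLAST tabular ("outfmt 6") column order: query, subject, percent
#' identity, alignment length, mismatches, gap openings, then 1-based
#' closed query/subject coordinates, E-value and score. Minus-strand hits
#' carry reversed subject coordinates, as BLAST does.
#'
#' @param hits output of [localAlign()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  ss <- ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end)
  se <- ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L)
  tab <- data.frame(
    hits$query_id, hits$subject_id,
    sprintf("%.2f", 100 * hits$identities / pmax(hits$aligned_cols, 1L)),
    hits$aligned_cols, hits$mismatches, hits$gaps,
    hits$q_start + 1L, hits$q_end, ss, se,
    format(hits$evalue, digits = 3), hits$score)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Lossless seed length for the ungapped similarity window filter
#'
#' A window of L columns with identity at least (or strictly above) `p`
#' tolerates `k_L` mismatches, which split the matches into at most
#' `k_L + 1` runs, one of which has length at least
#' `ceiling((L - k_L) / (k_L + 1))`. The safe seed is the minimum of that
#' bound over all window lengths from `minOverlap` to `maxLen`, capped at 16
#' (a shorter seed only adds candidates, so the cap keeps the filter
#' lossless).
#'
#' @param minOverlap minimum window length in columns.
#' @param maxLen longest window possible (length of the shorter sequence).
#' @param minIdentity identity fraction threshold.
#' @param strict logical: `TRUE` for a strict `>` identity comparison.
#' @return integer seed length >= 1.
#' @export
losslessSeedLen <- function(minOverlap, maxLen, minIdentity,
                            strict = FALSE) {
  L <- seq.int(minOverlap, max(minOverlap, maxLen))
  k <- if (strict) {
    ifelse(abs(L * (1 - minIdentity) - round(L * (1 - minIdentity))) < 1e-9,
           round(L * (1 - minIdentity)) - 1L,
           floor(L * (1 - minIdentity)))
  } else {
    floor(L * (1 - minIdentity) + 1e-9)
  }
  k <- pmax(k, 0)
  w <- min(ceiling((L - k) / (k + 1)))
  as.integer(max(1L, min(16L, w)))
}

#' Detect a high-identity ungapped window between two sequences
#'
#' TRUE iff some ungapped alignment window of at least `minOverlap`
#' consecutive columns, on either strand, reaches the identity fraction.
#' Detection seeds on exact words of the lossless length (see
#' [losslessSeedLen()]) and verifies candidate diagonals exhaustively, so
#' the outcome equals a full window scan. This is the cross-hybridization
#' criterion of the probe similarity filter (95% identity over 50 or more
#' consecutive bases, by default usage).
#'
#' @param a,b nucleotide character scalars.
#' @param minOverlap minimum window length in columns (default 50).
#' @param minIdentity identity fraction in (0, 1] (default 0.95).
#' @param strict logical; `TRUE` compares identity with `>` instead of `>=`.
#' @return list(found, strand, a_start, b_start, length, matches, identity)
#'   describing the best qualifying window; coordinates 0-based on the
#'   forward strands (for strand "-", `b_start` refers to the forward
#'   strand of `b`).
#' @export
hasSimilarWindow <- function(a, b, minOverlap = 50L, minIdentity = 0.95,
                             strict = FALSE) {
  stopifnot(minOverlap >= 1L, minIdentity > 0, minIdentity <= 1)
  maxLen <- min(nchar(a), nchar(b))
  if (maxLen < minOverlap) {
    return(list(found = FALSE, strand = NA_character_, a_start = NA_integer_,
                b_start = NA_integer_, length = NA_integer_,
                matches = NA_integer_, identity = NA_real_))
  }
  w <- losslessSeedLen(minOverlap, maxLen, minIdentity, strict)
  fwd <- window_best_cpp(a, b, as.integer(minOverlap), minIdentity, strict, w)
  brc <- revComp(b)
  rev <- window_best_cpp(a, brc, as.integer(minOverlap), minIdentity,
                         strict, w)
  pick_rev <- isTRUE(rev$found) &&
    (!isTRUE(fwd$found) || rev$identity > fwd$identity)
  if (pick_rev) {
    list(found = TRUE, strand = "-", a_start = rev$a_start,
         b_start = nchar(b) - (rev$b_start + rev$length),
         length = rev$length, matches = rev$matches,
         identity = rev$identity)
  } else if (isTRUE(fwd$found)) {
    list(found = TRUE, strand = "+", a_start = fwd$a_start,
         b_start = fwd$b_start, length = fwd$length,
         matches = fwd$matches, identity = fwd$identity)
  } else {
    list(found = FALSE, strand = NA_character_, a_start = NA_integer_,
         b_start = NA_integer_, length = NA_integer_,
         matches = NA_integer_, identity = NA_real_)
  }
}

#' All similar sequence pairs in a collection (seeded)
#'
#' Applies the [hasSimilarWindow()] criterion to every unordered pair in a
#' collection via a shared k-mer index, returning the qualifying pairs.
#' Used by the cross-hybridization filter of the probe selection and by the
#' assembly completeness categories.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param minOverlap,minIdentity,strict as in [hasSimilarWindow()].
#' @return data.frame(id_a, id_b, strand) of qualifying unordered pairs
#'   (a pair similar on both relative orientations appears twice, once per
#'   strand).
#' @export
similarSequencePairs <- function(seqs, minOverlap = 50L, minIdentity = 0.95,
                                 strict = FALSE) {
  x <- .as_named_chr(seqs)
  maxLen <- max(nchar(x))
  w <- losslessSeedLen(minOverlap, maxLen, minIdentity, strict)
  m <- similar_pairs_seeded_cpp(unname(x), as.integer(minOverlap),
                                minIdentity, strict, w)
  .pairs_df(m, names(x))
}

#' All similar sequence pairs, exhaustive audit oracle
#'
#' The seeding-free counterpart of [similarSequencePairs()]: every
#' unordered pair on both relative orientations is scanned over all
#' diagonals and all window lengths. Quadratic and slow by design; it
#' exists to audit that the seeded filter missed nothing.
#'
#' @inheritParams similarSequencePairs
#' @return data.frame(id_a, id_b, strand).
#' @export
auditSimilarPairs <- function(seqs, minOverlap = 50L, minIdentity = 0.95,
                              strict = FALSE) {
  x <- .as_named_chr(seqs)
  m <- similar_pairs_brute_cpp(unname(x), as.integer(minOverlap),
                               minIdentity, strict)
  .pairs_df(m, names(x))
}

.pairs_df <- function(m, ids) {
  out <- data.frame(id_a = ids[m[, 1L]], id_b = ids[m[, 2L]],
                    strand = ifelse(m[, 3L] == 1L, "+", "-"),
                    stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b, out$strand), , drop = FALSE]
}
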