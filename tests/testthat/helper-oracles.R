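# Independent oracles and fixture builders, kept deliberately naive.

rnd_seq <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

rnd_seqs <- function(n, L, prefix = "s") {
  setNames(vapply(rep(L, n), rnd_seq, character(1)),
           sprintf("%s%03d", prefix, seq_len(n)))
}

# plain scalar-loop affine-gap local alignment score (no seeding, no
# vectorization); gap of length g costs open + g * extend (negative args)
sw_score_oracle <- function(a, b, match = 1, mismatch = -2,
                            gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  go <- -gap_open; ge <- -gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i - 1, j] - ge, H[i - 1, j] - go - ge)
      F[i, j] <- max(F[i, j - 1] - ge, H[i, j - 1] - go - ge)
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H)
}

# Biostrings local alignment as an independent library oracle, both strands
bios_local_score <- function(a, b, match = 1, mismatch = -2,
                             gap_open = -5, gap_extend = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  sc <- function(x, y) Biostrings::score(Biostrings::pairwiseAlignment(
    x, y, type = "local", substitutionMatrix = mat,
    gapOpening = -gap_open, gapExtension = -gap_extend))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  max(sc(a, b), sc(a, rc))
}

# exhaustive six-frame stop-to-stop translation: returns the multiset of
# peptide strings (per frame) without any coordinate bookkeeping
orf_oracle <- function(seq, min_aa) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  peps <- character(0)
  for (s in c(seq, rc)) {
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3
      if (ncod < 1) next
      starts <- off + 3 * (seq_len(ncod) - 1) + 1
      codons <- substring(s, starts, starts + 2)
      aa <- Biostrings::GENETIC_CODE[codons]
      aa[is.na(aa)] <- "X"
      runs <- strsplit(paste(aa, collapse = ""), "*", fixed = TRUE)[[1]]
      peps <- c(peps, runs[nchar(runs) >= min_aa])
    }
  }
  sort(peps)
}

# exhaustive ungapped window scan (both strands), pure R, small inputs only
window_oracle <- function(a, b, min_overlap, min_identity, strict = FALSE) {
  scan1 <- function(x, y) {
    X <- strsplit(x, "")[[1]]; Y <- strsplit(y, "")[[1]]
    la <- length(X); lb <- length(Y)
    for (d in (-(lb - min_overlap)):(la - min_overlap)) {
      as <- max(0, d); bs <- max(0, -d)
      dl <- min(la - as, lb - bs)
      if (dl < min_overlap) next
      mvec <- (X[as + seq_len(dl)] == Y[bs + seq_len(dl)]) &
              (X[as + seq_len(dl)] != "N")
      cs <- c(0, cumsum(mvec))
      for (L in min_overlap:dl) {
        for (s0 in 0:(dl - L)) {
          mt <- cs[s0 + L + 1] - cs[s0 + 1]
          ok <- if (strict) mt > min_identity * L + 1e-9
                else mt >= min_identity * L - 1e-9
          if (ok) return(TRUE)
        }
      }
    }
    FALSE
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  scan1(a, b) || scan1(a, rc)
}

# independent window-score computation in base R
score_window_oracle <- function(w) {
  ch <- strsplit(w, "")[[1]]
  L <- length(ch)
  if (sum(ch == "N") > 0.10 * L + 1e-9) return(-Inf)
  gc <- mean(ch %in% c("G", "C"))
  hp <- max(rle(ch)$lengths)
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(w))), "")[[1]]
  # longest common substring of w and its reverse complement
  best <- 0
  dp <- matrix(0L, L + 1, L + 1)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (ch[i] != "N" && ch[i] == rc[j]) {
        dp[i + 1, j + 1] <- dp[i, j] + 1L
        if (dp[i + 1, j + 1] > best) best <- dp[i + 1, j + 1]
      }
    }
  }
  -abs(gc - 0.5) - 0.05 * max(hp - 4, 0) - 0.02 * max(best - 8, 0)
}

# a small call-matrix object built by hand
make_pcm <- function(probe_id, n, pos, flag, mean_si = 1000) {
  new("ProbeCallMatrix", calls = data.frame(
    probe_id = probe_id, n_measurements = as.integer(n),
    n_positive = as.integer(pos), n_flagged = as.integer(flag),
    mean_si = rep_len(mean_si, length(probe_id)), cv_si = 0.1,
    stringsAsFactors = FALSE))
}
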