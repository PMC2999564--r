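#' Read an EST/target FASTA file into a DNAStringSet
#'
#' Reads a multi-record FASTA (wrapped or unwrapped), upper-cases residues,
#' maps U to T, and validates that every record has a unique, non-empty
#' identifier and a non-empty sequence over the {A,C,G,T,N} alphabet. The
#' source tag (e.g. `"contig"`, `"singleton"`, `"sanger_ssh"`,
#' `"genbank_est"`, `"synthetic"`) is recorded in `mcols(x)$source`.
#'
#' @param path path to a FASTA file.
#' @param source source tag applied to all records, or a character vector
#'   recycled across records.
#' @return A [Biostrings::DNAStringSet] with ids as names and a `source`
#'   metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1", "ACGTACGT", ">t2", "ggggcccc"), fa)
#' readFastaRecords(fa)
#' @export
readFastaRecords <- function(path, source = "synthetic") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header: empty id at record ",
         which(!nzchar(ids))[1])
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N,U}")
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("record '", ids[which(empty)[1]], "' has an empty sequence")
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    source = rep_len(source, length(x)))
  x
}

#' Write sequence records to FASTA
#'
#' @param x a [Biostrings::DNAStringSet] (names become headers) or a named
#'   character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of nucleotide text
#'
#' Both probe orientations are assumed during design, so sequences move
#' between strands constantly; this is the character-vector convenience on
#' top of [Biostrings::reverseComplement()]. N maps to N; any other
#' character is an error.
#'
#' @param seq character vector of sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @examples
#' revComp(c("ACGT", "AAAC"))
#' @export
revComp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequence contains characters outside the {A,C,G,T,N} alphabet")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract open reading frames from all six frames
#'
#' Uses the stop-to-stop convention: in each of the six reading frames,
#' every maximal run of stop-free codons of at least `minAa` codons is
#' emitted as a peptide (no start codon required), translated with the
#' standard genetic code. A codon containing N translates to X and does not
#' terminate a run. Coordinates are 0-based half-open on the forward strand.
#'
#' @param x a [Biostrings::DNAStringSet], or a named character vector of
#'   sequences.
#' @param minAa minimum peptide length in amino acids (default 5).
#' @return data.frame(parent_id, frame, start_nt, end_nt, aa_seq) where
#'   frame is in {+1,+2,+3,-1,-2,-3} and `end_nt - start_nt` equals three
#'   times the peptide length.
#' @examples
#' extractOrfs(c(t1 = "TAAATGGCTGCTGCTGCTTAA"), minAa = 5)
#' @export
extractOrfs <- function(x, minAa = 5L) {
  stopifnot(minAa >= 1L)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    seqs <- x
  } else {
    seqs <- as.character(x)
  }
  out <- lapply(names(seqs), function(id) {
    .orfs_one(id, seqs[[id]], as.integer(minAa))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(parent_id = character(), frame = integer(),
                      start_nt = integer(), end_nt = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE)
  }
  res
}

.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
  unname(aa)
}

.orfs_one <- function(id, seq, min_aa) {
  L <- nchar(seq)
  if (L < 3L) return(NULL)
  rc <- revComp(seq)
  res <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    for (off in 0:2) {
      ncod <- (L - off) %/% 3L
      if (ncod < min_aa) next
      starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      aa <- .translate_codons(codons)
      stops <- c(0L, which(aa == "*"), ncod + 1L)
      for (k in seq_len(length(stops) - 1L)) {
        a <- stops[k] + 1L
        b <- stops[k + 1L] - 1L
        if (b - a + 1L < min_aa) next
        # codon positions [a, b] on strand s, 0-based nt coords on s:
        s0 <- off + 3L * (a - 1L)
        s1 <- off + 3L * b
        if (strand == 1L) {
          start_nt <- s0; end_nt <- s1
        } else {
          start_nt <- L - s1; end_nt <- L - s0
        }
        res[[length(res) + 1L]] <- data.frame(
          parent_id = id,
          frame = strand * (off + 1L),
          start_nt = start_nt, end_nt = end_nt,
          aa_seq = paste(aa[a:b], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

#' Write extracted peptides as FASTA
#'
#' Headers follow `parentid|frame|start-end` with 1-based closed
#' coordinates on the forward strand.
#'
#' @param peptides output of [extractOrfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(peptides, path) {
  hdr <- sprintf("%s|%+d|%d-%d", peptides$parent_id, peptides$frame,
                 peptides$start_nt + 1L, peptides$end_nt)
  x <- Biostrings::AAStringSet(setNames(peptides$aa_seq, hdr))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
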