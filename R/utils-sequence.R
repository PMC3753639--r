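#' Normalize a nucleotide sequence to uppercase DNA
#'
#' RNA input (`U`) is converted to its DNA representation (`T`); whitespace is
#' stripped. Ambiguity codes are rejected because every design rule in the
#' package operates on exact complementarity.
#'
#' @param x Character scalar, 5'->3' nucleotide sequence (DNA or RNA).
#' @return Character scalar in the alphabet `A`, `C`, `G`, `T`.
#' @export
#' @examples
#' as_dna("uagcagcacg")
as_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(gsub("\\s", "", x))
  x <- chartr("U", "T", x)
  if (!grepl("^[ACGT]*$", x)) {
    stop("sequence contains characters outside {A,C,G,U/T}: ", x, call. = FALSE)
  }
  x
}

#' Reverse complement of a DNA sequence
#'
#' @param x Character scalar (DNA or RNA; coerced with [as_dna()]).
#' @return Character scalar, the reverse complement in DNA alphabet.
#' @export
#' @examples
#' revcomp("AAATCGAGGGAGGGAG")
revcomp <- function(x) {
  x <- as_dna(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

#' Complement (no reversal) of a DNA sequence
#' @param x Character scalar.
#' @return Character scalar.
#' @keywords internal
#' @noRd
complement_dna <- function(x) chartr("ACGT", "TGCA", as_dna(x))

#' Length of the longest run of contiguous complementarity between two strands
#'
#' Scans every ungapped antiparallel alignment of `probe` against `target` and
#' returns the longest run of Watson-Crick base pairs. Used to check that
#' generic tails do not hybridize to the template they are appended for.
#'
#' @param probe,target Character scalars (DNA/RNA).
#' @return Integer scalar, the maximal complementary run length.
#' @export
max_complementary_run <- function(probe, target) {
  p <- strsplit(as_dna(probe), "")[[1]]
  trc <- strsplit(revcomp(target), "")[[1]]
  np <- length(p); nt <- length(trc)
  if (np == 0L || nt == 0L) return(0L)
  best <- 0L
  # slide probe along the reverse complement of the target; equality there
  # means complementarity to the target itself
  for (off in seq.int(-(np - 1L), nt - 1L)) {
    run <- 0L
    for (i in seq_len(np)) {
      j <- i + off
      if (j >= 1L && j <= nt && p[i] == trc[j]) {
        run <- run + 1L
        if (run > best) best <- run
      } else {
        run <- 0L
      }
    }
  }
  best
}

#' Read sequence templates from FASTA or plain text
#'
#' FASTA files (first non-blank character `>`) are parsed with
#' \pkg{Biostrings}; otherwise each non-empty line is taken as one sequence
#' and named `seq1`, `seq2`, ...
#'
#' @param path Path to a FASTA or plain-text sequence file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_templates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (startsWith(trimws(lines[[1]]), ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    seqs <- trimws(lines)
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  vapply(seqs, as_dna, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
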