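#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement, reversed. `N` maps to `N`. Lowercase
#' input is accepted and upper-cased; gap characters or any symbol outside
#' `{A,C,G,T,N}` are an error, since the reverse complement of a gapped
#' sequence is not defined here.
#'
#' @param seq A single character string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string (upper case).
#' @examples
#' reverse_complement("TGCCCGACGAT")  # "ATCGTCGGGCA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  if (nchar(s) == 0L) return(s)
  if (grepl("[^ACGTN]", s)) {
    stop("reverse_complement(): sequence contains gap or unknown characters")
  }
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

#' Translate an in-frame DNA sequence
#'
#' Translation under the standard nuclear genetic code. The frame is anchored
#' `frame_offset` bases into the sequence; a trailing partial codon is
#' dropped. Stop codons render as `*`; any codon containing `N` renders
#' as `X`.
#'
#' @param seq A character string over `{A,C,G,T,N}` (case-insensitive).
#' @param frame_offset 0, 1 or 2; bases skipped before the first codon.
#' @return Amino-acid string (possibly empty).
#' @examples
#' translate_dna("AAGTCTGAACTAGATCCC")  # "KSELDP"
#' @export
translate_dna <- function(seq, frame_offset = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    stop("translate_dna(): sequence contains gap or unknown characters")
  }
  s <- substr(s, frame_offset + 1L, nchar(s))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons), "X", unname(code[codons]))
  paste(aa, collapse = "")
}

# Grantham (1974) physicochemical distance matrix, shipped as a plain-text
# data file; validated on first load (symmetric, zero diagonal, off-diagonal
# range 5..215).
.grantham <- function() {
  if (is.null(.irswitch$grantham)) {
    path <- system.file("extdata", "grantham1974.csv", package = "irswitch")
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "integer"
    stopifnot(
      identical(rownames(m), colnames(m)),
      isTRUE(all.equal(m, t(m), check.attributes = FALSE)),
      all(diag(m) == 0L),
      min(m[upper.tri(m)]) == 5L,
      max(m) == 215L
    )
    .irswitch$grantham <- m
  }
  .irswitch$grantham
}

#' Grantham physicochemical distance between two amino acids
#'
#' Integer distances from Grantham's (1974) table, which combines amino-acid
#' composition, polarity and molecular volume; off-diagonal values range
#' from 5 (Leu/Ile) to 215 (Cys/Trp) with mean ~100.
#'
#' @param aa1,aa2 One-letter codes of standard amino acids.
#' @return Integer distance (0 when `aa1 == aa2`).
#' @examples
#' grantham_distance("C", "W")  # 215
#' @export
grantham_distance <- function(aa1, aa2) {
  m <- .grantham()
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  if (!all(c(aa1, aa2) %in% rownames(m))) {
    stop("grantham_distance(): not a standard amino acid: ",
         paste(setdiff(c(aa1, aa2), rownames(m)), collapse = ", "))
  }
  unname(m[aa1, aa2])
}

#' @rdname grantham_distance
#' @return `grantham_matrix()` returns the full symmetric 20 x 20 matrix.
#' @export
grantham_matrix <- function() .grantham()

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (wrapped lines tolerated; `-` gaps allowed).
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Assemble and validate a codon alignment
#'
#' A codon alignment is a named character vector of equal-length, upper-case
#' rows over `{A,C,G,T,N,-}` whose length is divisible by 3, with the reading
#' frame anchored at column 0. Rows may not carry an in-frame stop codon at
#' any non-terminal codon position (a stop in the final codon is allowed).
#'
#' @param seqs Named character vector of aligned sequences.
#' @return The validated alignment with class `codon_alignment`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("codon_alignment(): rows differ in length")
  if (widths[1L] %% 3L != 0L) stop("codon_alignment(): length not divisible by 3")
  if (any(grepl("[^ACGTN-]", seqs))) stop("codon_alignment(): invalid characters")
  n_codon <- widths[1L] %/% 3L
  if (n_codon > 1L) {
    stops <- c("TAA", "TAG", "TGA")
    for (id in names(seqs)) {
      cod <- substring(seqs[[id]], 3L * seq_len(n_codon - 1L) - 2L,
                       3L * seq_len(n_codon - 1L))
      if (any(cod %in% stops)) {
        stop("codon_alignment(): premature stop codon in '", id, "'")
      }
    }
  }
  structure(seqs, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment: %d taxa x %d columns (%d codons)\n",
              length(x), nchar(x[[1L]]), nchar(x[[1L]]) %/% 3L))
  invisible(x)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) codon_alignment(read_fasta(path))

# ---- internal coordinate helpers (0-based half-open throughout) ----

# strip gaps; attribute "map" gives, per ungapped position (1-based index),
# the 0-based alignment column it came from
strip_gaps <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  keep <- chars != "-"
  structure(paste(chars[keep], collapse = ""), map = which(keep) - 1L)
}

# substring by 0-based half-open interval
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)

# number of differing positions between equal-length strings
n_diffs <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}
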