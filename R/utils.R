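# Nucleotide alphabet helpers. Within-hairpin indices are 0-based throughout
# the package (genomic coordinates stay 1-based, VCF/GFF convention); these
# helpers therefore take/return 0-based indices where relevant.

RNA_BASES <- c("A", "C", "G", "U")

#' Convert a DNA string to RNA (T -> U), uppercased
#' @param x character vector of sequences
#' @return character vector in the RNA alphabet
#' @export
transcribe <- function(x) chartr("acgtuT", "ACGUUU", x)

#' Convert an RNA string to DNA (U -> T), uppercased
#' @param x character vector of sequences
#' @return character vector in the DNA alphabet
#' @export
to_dna <- function(x) chartr("acgutU", "ACGTTT", x)

#' Complement RNA bases
#' @param x character vector of RNA sequences
#' @return complemented sequences (same orientation)
#' @export
complement_rna <- function(x) chartr("ACGU", "UGCA", x)

#' Reverse-complement an RNA sequence
#' @param x character vector of RNA sequences
#' @return reverse complement
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_rna(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' 0-based sequence indexing helpers
#'
#' Within-hairpin positions are 0-based throughout the package; these
#' helpers read, replace, and slice characters at 0-based indices.
#' `subseq0` clips its inclusive bounds to the sequence.
#'
#' @param seq a single sequence string
#' @param idx0,from0,to0 0-based positions
#' @param base replacement character
#' @return a character scalar
#' @export
char_at <- function(seq, idx0) substr(seq, idx0 + 1L, idx0 + 1L)

#' @rdname char_at
#' @export
set_char_at <- function(seq, idx0, base) {
  substr(seq, idx0 + 1L, idx0 + 1L) <- base
  seq
}

#' @rdname char_at
#' @export
subseq0 <- function(seq, from0, to0) {
  n <- nchar(seq)
  from0 <- max(from0, 0L)
  to0 <- min(to0, n - 1L)
  if (to0 < from0) return("")
  substr(seq, from0 + 1L, to0 + 1L)
}

is_rna_seq <- function(x) grepl("^[ACGU]+$", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
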