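# Internal sequence helpers. DNA is handled as plain uppercase character
# strings; Biostrings is used where C-level speed matters.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T only).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACACTAG")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and validate a DNA string; IUPAC ambiguity codes are rejected.
check_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || anyNA(x)) {
    abort(sprintf("%s must be a character vector without NA", what))
  }
  x <- toupper(x)
  if (!allow_empty && any(!nzchar(x))) {
    abort(sprintf("%s must be non-empty", what))
  }
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (IUPAC ambiguity codes are not supported)", what))
  }
  x
}

# Insert `ins` into `x` after 0-based offset `pos0`.
str_insert <- function(x, pos0, ins) {
  paste0(substr(x, 1L, pos0), ins, substr(x, pos0 + 1L, nchar(x)))
}

# Delete `len` characters from `x` starting at 0-based offset `pos0`.
str_delete <- function(x, pos0, len) {
  paste0(substr(x, 1L, pos0), substr(x, pos0 + len + 1L, nchar(x)))
}

# Fixed-substring containment on either strand.
contains_either_strand <- function(seq, pattern) {
  grepl(pattern, seq, fixed = TRUE) | grepl(revcomp(pattern), seq, fixed = TRUE)
}

# Deterministic child seeds derived from one user seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}
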