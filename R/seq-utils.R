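# Low-level nucleotide string helpers. All sequences are plain upper-case
# character vectors over ACGT (N handled only at read intake, where it splits
# reads into unambiguous fragments).

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. Ambiguous
#' bases other than N are not supported.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement; it gives a strand-neutral key. Odd k
#' guarantees a k-mer is never its own reverse complement.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  pmin(x, revcomp(x))
}

# All k-mers of one sequence, in order; empty vector when too short.
kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (is.na(n) || n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

# Split sequences at ambiguous characters, returning clean ACGT fragments.
split_ambiguous <- function(seqs) {
  seqs <- toupper(seqs)
  frags <- unlist(strsplit(seqs, "[^ACGT]+"), use.names = FALSE)
  frags[nzchar(frags)]
}

# Fraction of A/T characters in a single sequence.
at_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(0)
  nchar(gsub("[^AT]", "", seq)) / n
}

# Hamming distance between the aligned prefixes of two strings
# (over min(nchar) positions).
hamming_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  sum(utf8ToInt(substr(a, 1, n)) != utf8ToInt(substr(b, 1, n)))
}

# Random DNA string (uses the current RNG stream).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply substitutions at given 1-based positions, choosing a different base.
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}
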