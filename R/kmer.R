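#' Count canonical k-mers in a read set
#'
#' Reads are split at ambiguous (non-ACGT) characters and every fragment of
#' length at least k contributes all of its k-mers, counted under the
#' canonical (strand-neutral) representation.
#'
#' @param reads Character vector of read sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param k Odd integer k-mer size, at least 3.
#' @return An object of class `kmer_table`: a list with elements `k` and
#'   `counts` (named integer vector keyed by canonical k-mer).
#' @export
#' @examples
#' count_kmers("ACGTA", 3)$counts
count_kmers <- function(reads, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L) {
    stop("k must be an odd integer >= 3")
  }
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  frags <- split_ambiguous(reads)
  frags <- frags[nchar(frags) >= k]
  if (length(frags) == 0) {
    return(structure(list(k = k, counts = integer(0)), class = "kmer_table"))
  }
  kms <- unlist(lapply(frags, kmerize, k = k), use.names = FALSE)
  can <- canonical_kmer(kms)
  dt <- data.table::data.table(kmer = can)
  tab <- dt[, .N, by = "kmer"]
  counts <- tab$N
  names(counts) <- tab$kmer
  structure(list(k = k, counts = counts), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d, %d canonical k-mers, total mass %d\n",
              x$k, length(x$counts), sum(x$counts)))
  invisible(x)
}

# Merge a k-mer table with a set of connectivity sequences: k-mers of `seqs`
# absent from `table` enter with count 1 (presence only, no read support).
# Returns list(table, protected) where `protected` holds exactly those
# rescued k-mers -- the connectivity that only the earlier, smaller-k pass
# could see, which must not fall to coverage-based cleaning.
augment_kmer_table <- function(table, seqs) {
  prot <- count_kmers(seqs, table$k)
  if (length(prot$counts) == 0) {
    return(list(table = table, protected = character(0)))
  }
  extra <- setdiff(names(prot$counts), names(table$counts))
  counts <- c(table$counts, stats::setNames(rep(1L, length(extra)), extra))
  list(
    table = structure(list(k = table$k, counts = counts), class = "kmer_table"),
    protected = extra
  )
}
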