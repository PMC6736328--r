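# File formats. FASTA/FASTQ go through Biostrings (gzip-transparent);
# GFA 1.0 is written and read directly (segment lines carry k-mer count
# and mean-coverage tags, link lines the (k-1)-mer overlap).

#' Read a FASTQ file
#'
#' Gzip-transparent; qualities are parsed but not used by the assembler.
#'
#' @param path FASTQ(.gz) file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Read a FASTA file
#' @param path FASTA(.gz) file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- stats::setNames(as.character(x), names(x))
  out
}

#' Write sequences as FASTA
#' @param seqs Named character vector (or contig data.frame with `name`
#'   and `seq` columns).
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$name)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write paired reads as FASTQ
#'
#' Plain-text or gzip output depending on the file extension; constant
#' qualities (the assembler never uses them).
#'
#' @param reads Character vector of sequences.
#' @param path Output path (`.gz` for gzip).
#' @param ids Optional read names.
#' @return Invisibly, the path.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Write the assembly graph in GFA 1.0
#'
#' One segment line per edge twin pair with `KC` (k-mer count mass) and
#' `km` (mean k-mer coverage) tags; link lines carry the (k-1)M overlap.
#'
#' @param graph A `cdbg` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gfa <- function(graph, path) {
  e <- graph$edges
  k <- graph$k
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tkm:i:%d", k), con)
  rep_row <- pmin(seq_len(nrow(e)), if (nrow(e)) e$twin else integer(0))
  seg_ids <- match(rep_row, sort(unique(rep_row)))
  if (nrow(e)) {
    reps <- sort(unique(rep_row))
    nk <- edge_nk(graph, reps)
    writeLines(sprintf("S\tedge_%d\t%s\tKC:i:%d\tkm:f:%g",
                       seq_along(reps), e$seq[reps],
                       as.integer(round(e$cov[reps] * nk)), e$cov[reps]), con)
    # oriented link lines: edge i is segment seg_ids[i] with orientation
    # '+' when i is the representative row
    orient <- ifelse(seq_len(nrow(e)) == rep_row, "+", "-")
    adj <- adjacency(graph)
    seen <- character(0)
    for (i in seq_len(nrow(e))) {
      outs <- adj$out[[adj$tid[i]]]
      for (j in outs) {
        l1 <- sprintf("edge_%d\t%s\tedge_%d\t%s", seg_ids[i], orient[i],
                      seg_ids[j], orient[j])
        # twin-mirror of the link
        l2 <- sprintf("edge_%d\t%s\tedge_%d\t%s",
                      seg_ids[e$twin[j]], orient[e$twin[j]],
                      seg_ids[e$twin[i]], orient[e$twin[i]])
        if (l1 %in% seen || l2 %in% seen) next
        seen <- c(seen, l1)
        writeLines(sprintf("L\t%s\t%dM", l1, k - 1L), con)
      }
    }
  }
  invisible(path)
}

#' Read a GFA 1.0 assembly graph
#'
#' Restores edge sequences, coverage tags and twin pairing from a
#' [write_gfa()] file. Link lines are implied by shared (k-1)-mer vertex
#' labels and are not needed to rebuild the graph.
#'
#' @param path GFA file path.
#' @return A `cdbg` object.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[startsWith(lines, "H")][1], "\t")[[1]]
  km <- hd[startsWith(hd, "km:i:")]
  k <- as.integer(sub("km:i:", "", km))
  ss <- strsplit(lines[startsWith(lines, "S")], "\t")
  seqs <- vapply(ss, `[[`, character(1), 3L)
  covs <- vapply(ss, function(x) {
    tag <- x[startsWith(x, "km:f:")]
    if (length(tag)) as.numeric(sub("km:f:", "", tag[1])) else 1
  }, numeric(1))
  graph_from_edges(k, seqs, covs)
}

#' Write run parameters as YAML
#' @param params A list ([assembly_params()] or [sim_config()] work).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
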