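# Read-to-graph mapping by exact k-mer anchoring. Each mate is anchored to
# the oriented edge collecting the majority of its unique k-mer hits; no
# full alignment is attempted. This is sufficient at the scale the package
# targets and keeps the mapper free of external dependencies.

# Anchor a set of sequences. Every oriented edge collecting unique exact
# k-mer hits of a read is a placement of that read; a read crossing an
# edge junction therefore supports all edges it touches. Returns one row
# per (read, edge) with the k-mer hit count and the median implied offset
# of the read start on the edge (0-based, may be negative for overhangs).
anchor_reads <- function(seqs, index, k, stride = 5L) {
  empty <- data.table::data.table(read = integer(0), edge = integer(0),
                                  off = integer(0), nhit = integer(0))
  n <- length(seqs)
  if (n == 0 || nrow(index) == 0) return(empty)
  lens <- nchar(seqs)
  lst <- lapply(seq_len(n), function(i) {
    if (lens[i] < k) return(NULL)
    kp <- unique(c(seq.int(1L, lens[i] - k + 1L, by = stride),
                   lens[i] - k + 1L))
    data.table::data.table(read = i, kpos = kp,
                           kmer = substring(seqs[i], kp, kp + k - 1L))
  })
  dt <- data.table::rbindlist(lst)
  if (nrow(dt) == 0) return(empty)
  hits <- index[dt, on = "kmer", nomatch = NULL]
  if (nrow(hits) == 0) return(empty)
  hits[, off := pos - (kpos - 1L)]
  hits[, list(off = as.integer(stats::median(off)), nhit = .N),
       by = c("read", "edge")]
}

#' Map read pairs onto the assembly graph
#'
#' Anchors each mate by its unique exact k-mer hits (majority vote over
#' edges); the second mate is reverse-complemented first so both mates of a
#' proper pair anchor to the same strand. Unanchorable or ambiguous mates
#' drop the pair. The insert size is estimated from pairs landing on a
#' single edge. The index is symmetrised under twin substitution, so a pair
#' recorded on edges (a, b) equally supports (twin(b), twin(a)).
#'
#' @param graph A `cdbg` object (a simplified graph is typical).
#' @param read_pairs List with character vectors `r1` and `r2`.
#' @param stride Anchor every stride-th k-mer of a mate (plus the last).
#' @return An object of class `paired_links`: list with `pairs` (a
#'   data.table of edge/offset anchors per mate), `insert_mean`,
#'   `insert_sd`, `read_length`.
#' @export
map_read_pairs <- function(graph, read_pairs, stride = 5L) {
  idx <- edge_kmer_index(graph)
  r1 <- toupper(read_pairs$r1)
  r2r <- revcomp(toupper(read_pairs$r2))
  a1 <- anchor_reads(r1, idx, graph$k, stride)
  a2 <- anchor_reads(r2r, idx, graph$k, stride)
  rl <- if (length(r1)) as.integer(stats::median(nchar(r1))) else 0L
  data.table::setnames(a1, c("edge", "off", "nhit"), c("e1", "off1", "n1"))
  data.table::setnames(a2, c("edge", "off", "nhit"), c("e2", "off2", "n2"))
  pairs <- merge(a1, a2, by = "read", allow.cartesian = TRUE)
  pairs[, id := read]
  n_mapped <- length(unique(pairs$id))
  # insert size from pairs landing on a single edge (best placement per
  # mate to avoid double counting)
  b1 <- a1[order(-a1$n1)][!duplicated(read)]
  b2 <- a2[order(-a2$n2)][!duplicated(read)]
  same <- merge(b1, b2, by = "read")
  same <- same[same$e1 == same$e2]
  ins <- same$off2 + rl - same$off1
  ins <- ins[ins > 0 & ins < 10000]
  im <- if (length(ins) >= 2) mean(ins) else 2.5 * rl
  isd <- if (length(ins) >= 2) max(stats::sd(ins), 1) else 0.25 * max(im, 1)
  # symmetrise under twin substitution with strand flip
  tw <- graph$edges$twin
  elen <- nchar(graph$edges$seq)
  mirr <- data.table::data.table(
    read = pairs$read,
    e1 = tw[pairs$e2], off1 = elen[pairs$e2] - (pairs$off2 + rl),
    n1 = pairs$n2,
    e2 = tw[pairs$e1], off2 = elen[pairs$e1] - (pairs$off1 + rl),
    n2 = pairs$n1, id = pairs$id
  )
  allp <- rbind(pairs, mirr)
  structure(list(pairs = allp, insert_mean = im, insert_sd = isd,
                 read_length = rl, n_mapped = n_mapped),
            class = "paired_links")
}

#' @export
print.paired_links <- function(x, ...) {
  cat(sprintf(
    "paired_links: %d mapped pairs, insert %.1f +/- %.1f, read length %d\n",
    x$n_mapped, x$insert_mean, x$insert_sd, x$read_length))
  invisible(x)
}

#' Annotate edges with strand-specific coverage
#'
#' For a stranded library, reads are first oriented to the transcript
#' (sense) strand -- for the reverse-forward (RF) protocol the first mate is
#' antisense and is reverse-complemented, for forward-reverse (FR) the
#' second mate is -- and then mapped by exact k-mer placement. Each
#' placement increments the forward strand count of the edge position it
#' lands on, giving positional strand coverage. Mean forward coverage of an
#' edge equals the mean reverse coverage of its twin:
#' `cov_plus(e) = cov_minus(twin(e))`.
#'
#' @param graph A `cdbg` object.
#' @param read_pairs List with character vectors `r1` and `r2`.
#' @param protocol `"RF"` or `"FR"`; with `"unstranded"` the call warns and
#'   returns the graph unchanged.
#' @return The graph with `cov_plus`/`cov_minus` populated and positional
#'   arrays stored for strand-based edge splitting.
#' @export
annotate_strand_coverage <- function(graph, read_pairs,
                                     protocol = c("RF", "FR", "unstranded")) {
  protocol <- match.arg(protocol)
  if (protocol == "unstranded") {
    warning("library is unstranded; strand coverage not annotated")
    return(graph)
  }
  e <- graph$edges
  n <- nrow(e)
  if (n == 0) return(graph)
  r1 <- toupper(read_pairs$r1); r2 <- toupper(read_pairs$r2)
  sense <- if (protocol == "RF") c(revcomp(r1), r2) else c(r1, revcomp(r2))
  k <- graph$k
  idx <- edge_kmer_index(graph)
  frags <- split_ambiguous(sense)
  frags <- frags[nchar(frags) >= k]
  nk <- edge_nk(graph)
  pc <- lapply(nk, function(m) numeric(m))
  if (length(frags) && nrow(idx)) {
    lst <- lapply(frags, function(s) data.table::data.table(kmer = kmerize(s, k)))
    dt <- data.table::rbindlist(lst)
    hits <- idx[dt, on = "kmer", nomatch = NULL]
    if (nrow(hits)) {
      cnt <- hits[, .N, by = c("edge", "pos")]
      for (r in seq_len(nrow(cnt))) {
        ei <- cnt$edge[r]
        pc[[ei]][cnt$pos[r] + 1L] <- pc[[ei]][cnt$pos[r] + 1L] + cnt$N[r]
      }
    }
  }
  cp <- vapply(pc, function(x) if (length(x)) mean(x) else 0, numeric(1))
  graph$edges$cov_plus <- cp
  graph$edges$cov_minus <- cp[e$twin]
  graph$pcov_plus <- pc
  graph
}
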