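# Two-pass iterative assembly. A lower k restores low-covered regions where
# read overlaps are short; the main pass at a higher k gives a less tangled
# graph. Edges from the first pass enter the second as protected
# connectivity sequences: their k-mers cannot be deleted by coverage-based
# rules, but coverage itself is always computed from the reads.

#' Choose k-mer sizes from the read length
#'
#' The main (higher) k is the largest odd number not exceeding
#' `read_length / 2 - 1`; the lower k is the largest odd number not
#' exceeding `read_length / 3`, floored at 29 (smaller values sharply
#' increase the chance of two transcripts sharing a k-mer and hence of
#' chimeric contigs). If the floor pushes the lower k to or past the higher
#' one, a single-k plan at the higher k is returned.
#'
#' @param read_length Read length in bp, at least 35.
#' @return A list of class `kplan` with `k_low`, `k_high`, `single_k`.
#' @export
#' @examples
#' select_kmer_sizes(100)
select_kmer_sizes <- function(read_length) {
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 35L) {
    stop("read_length must be at least 35")
  }
  largest_odd <- function(x) { v <- as.integer(floor(x)); v - (1L - v %% 2L) }
  k_high <- largest_odd(read_length / 2 - 1)
  k_low <- max(largest_odd(read_length / 3), 29L)
  single <- k_low >= k_high
  if (single) k_low <- k_high
  structure(list(k_low = k_low, k_high = k_high, single_k = single),
            class = "kplan")
}

#' @export
print.kplan <- function(x, ...) {
  if (x$single_k) cat(sprintf("k plan: single k = %d\n", x$k_high))
  else cat(sprintf("k plan: k_low = %d, k_high = %d\n", x$k_low, x$k_high))
  invisible(x)
}

#' Close coverage gaps between tips using overlaps and read pairs
#'
#' Joins a dead-end tip to a dead-start tip when either (a) their sequences
#' share an exact suffix-prefix overlap of at least `L_ov` bp and at least
#' `N_ov` read pairs connect them, or (b) at least `N_min` read pairs
#' connect them regardless of overlap. A tip with several eligible partners
#' is left alone (ambiguity breeds misassemblies), a tip is never glued to
#' its own twin (that would manufacture a hairpin), and the twin pair of a
#' glued junction is glued symmetrically.
#'
#' @param graph A `cdbg` object.
#' @param links A [map_read_pairs()] index on the same graph.
#' @param params [assembly_params()].
#' @return The graph with joined tips, re-condensed.
#' @export
close_gaps <- function(graph, links, params = assembly_params()) {
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  adj <- adjacency(graph)
  dead_end <- which(adj$outdeg[adj$tid] == 0L)
  dead_start <- which(adj$indeg[adj$fid] == 0L)
  if (length(dead_end) == 0 || length(dead_start) == 0) return(graph)

  lens <- nchar(e$seq)
  rl <- links$read_length
  win <- links$insert_mean + 2 * links$insert_sd
  pr <- links$pairs
  # pairs whose first mate sits within the insert window of its edge's end
  # and whose second mate sits near its edge's start
  prw <- pr[lens[pr$e1] - pr$off1 <= win & pr$off2 + rl <= win + rl]
  supp <- prw[, list(N = length(unique(id))), by = c("e1", "e2")]

  pair_count <- function(a, b) {
    r <- supp[supp$e1 == a & supp$e2 == b]
    if (nrow(r)) r$N else 0L
  }
  max_overlap <- function(a, b) {
    sa <- e$seq[a]; sb <- e$seq[b]
    top <- min(lens[a], lens[b], graph$k - 1L)
    for (ov in seq.int(top, 1L)) {
      if (substr(sa, lens[a] - ov + 1L, lens[a]) == substr(sb, 1L, ov))
        return(ov)
    }
    0L
  }

  # candidate partners per dead-end tip
  used <- logical(nrow(e))
  joins <- list()
  for (a in dead_end) {
    if (used[a]) next
    partners <- integer(0)
    meta <- list()
    for (b in dead_start) {
      if (b == a || b == e$twin[a] || used[b]) next
      np <- pair_count(a, b)
      ov <- max_overlap(a, b)
      elig_a <- ov >= params$L_ov && np >= params$N_ov
      elig_b <- np >= params$N_min
      if (!elig_a && !elig_b) next
      partners <- c(partners, b)
      meta[[length(partners)]] <- list(ov = if (elig_a) ov else 0L, np = np)
    }
    if (length(partners) != 1L) next            # unglued on ambiguity
    b <- partners[1L]
    # reverse ambiguity: does b accept another dead-end tip?
    rivals <- 0L
    for (a2 in dead_end) {
      if (a2 == b || a2 == e$twin[b] || used[a2]) next
      np <- pair_count(a2, b)
      if ((max_overlap(a2, b) >= params$L_ov && np >= params$N_ov) ||
          np >= params$N_min) rivals <- rivals + 1L
    }
    if (rivals != 1L) next
    m <- meta[[1L]]
    ov <- m$ov
    if (ov == 0L) {
      # pair-only junction: negative implied gap falls back to a short
      # exact overlap (>= 4 bp); otherwise direct concatenation
      sel <- prw[prw$e1 == a & prw$e2 == b]
      gap <- stats::median(links$insert_mean - (lens[a] - sel$off1) -
                             (sel$off2 + rl))
      if (is.na(gap)) next
      if (gap < 0) {
        ov4 <- max_overlap(a, b)
        if (ov4 >= 4L) ov <- ov4 else next
      }
    }
    joins[[length(joins) + 1L]] <- list(a = a, b = b, ov = ov)
    used[c(a, b, e$twin[a], e$twin[b])] <- TRUE
  }
  if (length(joins) == 0) return(graph)

  nk <- lens - graph$k + 1L
  new_rows <- list()
  drop <- integer(0)
  for (j in joins) {
    a <- j$a; b <- j$b
    sj <- paste0(e$seq[a], substring(e$seq[b], j$ov + 1L))
    covj <- (e$cov[a] * nk[a] + e$cov[b] * nk[b]) / (nk[a] + nk[b])
    cpj <- (e$cov_plus[a] * nk[a] + e$cov_plus[b] * nk[b]) / (nk[a] + nk[b])
    cmj <- (e$cov_minus[a] * nk[a] + e$cov_minus[b] * nk[b]) / (nk[a] + nk[b])
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      from = e$from[a], to = e$to[b], seq = sj, cov = covj,
      cov_plus = cpj, cov_minus = cmj, twin = NA_integer_,
      self_rc = FALSE,
      protected = e$protected[a] || e$protected[b],
      stringsAsFactors = FALSE
    )
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      from = e$to[b] |> revcomp(), to = e$from[a] |> revcomp(),
      seq = revcomp(sj), cov = covj, cov_plus = cmj, cov_minus = cpj,
      twin = NA_integer_, self_rc = FALSE,
      protected = e$protected[a] || e$protected[b],
      stringsAsFactors = FALSE
    )
    drop <- c(drop, a, b)
  }
  keep <- setdiff(seq_len(nrow(e)), unique(c(drop, e$twin[drop])))
  base <- e[keep, , drop = FALSE]
  base$twin <- match(e$twin[keep], keep)
  extra <- do.call(rbind, new_rows)
  nb <- nrow(base)
  extra$twin <- nb + seq_len(nrow(extra)) + rep(c(1L, -1L), nrow(extra) / 2L)
  g2 <- new_cdbg(graph$k, rbind(base, extra))
  g2$edges$self_rc <- g2$edges$twin == seq_len(nrow(g2$edges))
  recondense(g2)
}

#' Two-pass graph construction with gap closing
#'
#' Pass 1 builds and simplifies the graph at the lower k from the reads.
#' Pass 2 rebuilds at the higher k from the reads plus the pass-1 edge
#' sequences; pass-1-derived k-mers are protected from coverage-based
#' removal (their read coverage at the higher k may be zero in exactly the
#' low-coverage stretches the lower k was able to bridge). Read pairs are
#' then mapped, gaps between tips closed, and a final cleaning pass run.
#' For stranded libraries strand coverage is annotated and oppositely
#' dominated edges are split before gap closing.
#'
#' @param read_pairs List with character vectors `r1`, `r2`.
#' @param plan A [select_kmer_sizes()] plan.
#' @param params [assembly_params()].
#' @param protocol `"unstranded"`, `"RF"` or `"FR"`.
#' @param keep_raw Also return the unsimplified higher-k graph (debugging).
#' @return List with the final `graph`, `links` mapped on it, and
#'   optionally `raw_graph`.
#' @export
two_stage_assemble <- function(read_pairs, plan,
                               params = assembly_params(),
                               protocol = "unstranded", keep_raw = FALSE) {
  reads <- c(read_pairs$r1, read_pairs$r2)
  rl <- if (length(reads)) as.integer(stats::median(nchar(reads))) else 0L
  protected <- character(0)
  if (!plan$single_k && length(reads)) {
    t1 <- count_kmers(reads, plan$k_low)
    g1 <- build_condensed_graph(t1)
    g1 <- simplify_graph(g1, rl, params)
    e1 <- g1$edges
    if (nrow(e1)) {
      seeds <- e1$seq[seq_len(nrow(e1)) <= e1$twin]
      aug <- augment_kmer_table(count_kmers(reads, plan$k_high), seeds)
      t2 <- aug$table
      protected <- aug$protected
    } else {
      t2 <- count_kmers(reads, plan$k_high)
    }
  } else {
    t2 <- count_kmers(reads, plan$k_high)
  }
  if (length(t2$counts) == 0) {
    g <- new_cdbg(plan$k_high, empty_edges())
    return(list(graph = g,
                links = map_read_pairs(g, list(r1 = character(0),
                                               r2 = character(0)))))
  }
  g <- build_condensed_graph(t2, protected = protected)
  g_raw <- if (keep_raw) g else NULL
  g <- simplify_graph(g, rl, params)
  if (protocol %in% c("RF", "FR")) {
    g <- annotate_strand_coverage(g, read_pairs, protocol)
    g <- split_edges_by_strand(g, params)
  }
  links <- map_read_pairs(g, read_pairs)
  g2 <- close_gaps(g, links, params)
  changed <- !identical(graph_signature(g2), graph_signature(g))
  g <- simplify_graph(g2, rl, params)
  if (protocol %in% c("RF", "FR")) {
    g <- annotate_strand_coverage(g, read_pairs, protocol)
  }
  links <- if (changed || protocol %in% c("RF", "FR"))
    map_read_pairs(g, read_pairs) else links
  list(graph = g, links = links, raw_graph = g_raw)
}
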