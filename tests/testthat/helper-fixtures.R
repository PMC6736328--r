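# Shared fixtures: everything is generated in code, nothing on disk.

rdna <- function(n) rnaforge:::random_dna(n)

# Uniformly tiled error-free reads over a sequence (plus reverse mates at a
# fixed shift), handy for deterministic coverage layouts.
tiled_pairs <- function(seq, starts, rl = 100L, shift = 60L) {
  r1 <- substring(seq, starts, starts + rl - 1L)
  r2 <- revcomp(substring(seq, starts + shift, starts + shift + rl - 1L))
  keep <- nchar(r1) == rl & nchar(r2) == rl
  list(r1 = r1[keep], r2 = r2[keep])
}

# Independent condensed-graph oracle: raw (k-1)-overlap graph built k-mer
# by k-mer with igraph, condensed by naive walking. Returns a sorted
# character vector of "canonical seq@cov" keys, one per twin pair.
oracle_condensed <- function(table) {
  k <- table$k
  can <- names(table$counts)
  ok <- c(can, revcomp(can))
  cnt <- c(unname(table$counts), unname(table$counts))
  pref <- substr(ok, 1L, k - 1L)
  suff <- substr(ok, 2L, k)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pref, to = suff, label = seq_along(ok)),
    directed = TRUE)
  vn <- igraph::V(g)$name
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  internal <- indeg == 1 & outdeg == 1
  edf <- igraph::as_data_frame(g, what = "edges")
  used <- logical(nrow(edf))
  out_edges_of <- split(seq_len(nrow(edf)), edf$from)
  res <- character(0)
  walk_from <- function(ei) {
    ids <- integer(0)
    repeat {
      ids <- c(ids, ei)
      used[ei] <<- TRUE
      v <- edf$to[ei]
      if (!internal[[match(v, vn)]]) break
      nxt <- out_edges_of[[v]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      ei <- nxt[1]
    }
    ids
  }
  emit <- function(ids) {
    kms <- ok[as.integer(edf$label[ids])]
    seqv <- paste0(kms[1], paste(substr(kms[-1], k, k), collapse = ""))
    covv <- mean(cnt[as.integer(edf$label[ids])])
    res <<- c(res, paste0(pmin(seqv, revcomp(seqv)), "@", signif(covv, 8)))
  }
  starts <- which(!internal[match(edf$from, vn)])
  for (ei in starts) if (!used[ei]) emit(walk_from(ei))
  for (ei in seq_len(nrow(edf))) if (!used[ei]) emit(walk_from(ei))  # cycles
  sort(res)            # one key per oriented edge
}

# Key set of an implementation graph in the same format (one per row).
graph_keys <- function(g) {
  e <- g$edges
  sort(paste0(pmin(e$seq, revcomp(e$seq)), "@", signif(e$cov, 8)))
}
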