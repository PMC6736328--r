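# Bidirected condensed de Bruijn graph.
#
# Representation: every edge is stored in both orientations as separate rows
# of `g$edges`; `twin` holds the row index of the reverse-complement copy
# (twin == own index for palindromic, self-reverse-complement edges, which
# are flagged `self_rc`). Vertices are (k-1)-mer labels carried in `from`/
# `to`; strand-split edges receive synthetic detached labels so they can
# never re-condense with their former neighbours. Row indices double as
# edge ids and are reassigned by every rebuilding operation.

new_cdbg <- function(k, edges, pcov_plus = NULL) {
  rownames(edges) <- NULL
  g <- list(k = as.integer(k), edges = edges, pcov_plus = pcov_plus)
  class(g) <- "cdbg"
  g
}

empty_edges <- function() {
  data.frame(
    from = character(0), to = character(0), seq = character(0),
    cov = numeric(0), cov_plus = numeric(0), cov_minus = numeric(0),
    twin = integer(0), self_rc = logical(0), protected = logical(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cdbg <- function(x, ...) {
  ne <- nrow(x$edges)
  cat(sprintf(
    "condensed de Bruijn graph: k = %d, %d edges (%d twin pairs), total length %d bp\n",
    x$k, ne, (ne + sum(x$edges$self_rc)) %/% 2L,
    if (ne) sum(nchar(x$edges$seq)) else 0L
  ))
  invisible(x)
}

# Number of k-mers spelled by an edge.
edge_nk <- function(g, idx = seq_len(nrow(g$edges))) {
  nchar(g$edges$seq[idx]) - g$k + 1L
}

# Out-/in-adjacency: named list vertex label -> integer edge row indices.
out_map <- function(g) split(seq_len(nrow(g$edges)), g$edges$from)
in_map <- function(g) split(seq_len(nrow(g$edges)), g$edges$to)

adj_count <- function(map, v) {
  x <- map[[v]]
  if (is.null(x)) 0L else length(x)
}

# Decompose a successor function (each node has at most one predecessor and
# one successor) into maximal chains. `starts` are nodes without a usable
# predecessor; remaining unvisited nodes lie on pure cycles.
walk_chains <- function(n, nxt, starts) {
  visited <- logical(n)
  chains <- list()
  cyc <- logical(0)
  buf <- integer(n)
  for (s in starts) {
    if (visited[s]) next
    i <- s; len <- 0L
    repeat {
      len <- len + 1L; buf[len] <- i; visited[i] <- TRUE
      j <- nxt[i]
      if (is.na(j) || visited[j]) break
      i <- j
    }
    chains[[length(chains) + 1L]] <- buf[seq_len(len)]
    cyc[length(chains)] <- FALSE
  }
  for (s in seq_len(n)) {
    if (visited[s]) next
    i <- s; len <- 0L
    repeat {
      len <- len + 1L; buf[len] <- i; visited[i] <- TRUE
      j <- nxt[i]
      if (is.na(j) || visited[j]) break
      i <- j
    }
    chains[[length(chains) + 1L]] <- buf[seq_len(len)]
    cyc[length(chains)] <- TRUE
  }
  list(chains = chains, cycle = cyc)
}

# Rotate cyclic chains so each cycle's representation is the exact
# reverse complement of its twin cycle's representation.
align_twin_cycles <- function(chains, cycles, twin_unit) {
  if (!any(cycles)) return(chains)
  n <- sum(lengths(chains))
  chain_of <- integer(n)
  for (i in seq_along(chains)) chain_of[chains[[i]]] <- i
  done <- logical(length(chains))
  for (i in which(cycles)) {
    if (done[i]) next
    done[i] <- TRUE
    ci <- chains[[i]]
    want <- twin_unit[ci[length(ci)]]
    j <- chain_of[want]
    if (j == i) next                 # self-reverse-complement cycle
    done[j] <- TRUE
    cj <- chains[[j]]
    p <- match(want, cj)
    if (!is.na(p) && p > 1L) {
      chains[[j]] <- c(cj[p:length(cj)], cj[seq_len(p - 1L)])
    }
  }
  chains
}

#' Build a condensed de Bruijn graph from a k-mer table
#'
#' Expands the canonical k-mer set into both orientations, links k-mers
#' overlapping by k-1 characters, and contracts every maximal non-branching
#' path into a single edge. Edge coverage is the mean canonical count of the
#' constituent k-mers; twin edges carry identical coverage by construction.
#'
#' @param table A [count_kmers()] result.
#' @param protected Optional character vector of canonical k-mers to protect
#'   from coverage-based removal; edges whose k-mers are mostly protected
#'   are flagged.
#' @return An object of class `cdbg`.
#' @export
build_condensed_graph <- function(table, protected = character(0)) {
  k <- table$k
  can <- names(table$counts)
  if (length(can) == 0) return(new_cdbg(k, empty_edges()))
  nc <- length(can)
  rc <- revcomp(can)
  ok <- c(can, rc)                      # oriented k-mers (k odd: all distinct)
  cnt <- c(unname(table$counts), unname(table$counts))
  prot <- if (length(protected)) rep(can %in% protected, 2L) else
    rep(FALSE, length(ok))
  rc_of <- c(seq.int(nc + 1L, 2L * nc), seq_len(nc))

  n <- length(ok)
  pref <- substr(ok, 1L, k - 1L)
  suff <- substr(ok, 2L, k)
  verts <- unique(c(pref, suff))
  fid <- match(pref, verts)
  tid <- match(suff, verts)
  outdeg <- tabulate(fid, length(verts))
  indeg <- tabulate(tid, length(verts))
  out1 <- integer(length(verts))
  out1[fid] <- seq_len(n)               # valid where outdeg == 1
  nxt <- ifelse(outdeg[tid] == 1L & indeg[tid] == 1L, out1[tid], NA_integer_)
  nxt[!is.na(nxt) & nxt == seq_len(n)] <- NA_integer_   # 1-kmer self loop
  haspre <- indeg[fid] == 1L & outdeg[fid] == 1L

  wk <- walk_chains(n, nxt, which(!haspre))
  chains <- align_twin_cycles(wk$chains, wk$cycle, rc_of)
  last_char <- substr(ok, k, k)

  m <- length(chains)
  seqs <- character(m); from <- character(m); to <- character(m)
  cov <- numeric(m); prot_frac <- numeric(m)
  last_of <- integer(m)
  chain_of <- integer(n)
  for (i in seq_len(m)) {
    idx <- chains[[i]]
    chain_of[idx] <- i
    seqs[i] <- if (length(idx) == 1L) ok[idx] else
      paste0(ok[idx[1L]], paste(last_char[idx[-1L]], collapse = ""))
    from[i] <- pref[idx[1L]]
    to[i] <- suff[idx[length(idx)]]
    cov[i] <- mean(cnt[idx])
    prot_frac[i] <- mean(prot[idx])
    last_of[i] <- idx[length(idx)]
  }
  twin <- chain_of[rc_of[last_of]]

  edges <- data.frame(
    from = from, to = to, seq = seqs, cov = cov,
    cov_plus = 0, cov_minus = 0, twin = twin,
    self_rc = twin == seq_len(m), protected = prot_frac > 0,
    stringsAsFactors = FALSE
  )
  new_cdbg(k, edges)
}

#' Construct a condensed graph directly from edge sequences
#'
#' Convenience constructor for fixtures and tests: takes one sequence per
#' twin pair together with a coverage value, adds the reverse-complement
#' copies, derives vertex labels from the (k-1)-mer ends and pairs twins.
#' Sequences must already be condensed (the function does not merge them).
#'
#' @param k K-mer size the sequences were built with.
#' @param seqs Character vector of edge sequences (length >= k each).
#' @param cov Numeric vector of mean k-mer coverages (recycled).
#' @param cov_plus Optional forward-strand coverages (recycled).
#' @param protected Logical, recycled; protects edges from coverage-based
#'   removal.
#' @return A `cdbg` object.
#' @export
graph_from_edges <- function(k, seqs, cov = 1, cov_plus = NULL,
                             protected = FALSE) {
  stopifnot(all(nchar(seqs) >= k))
  nf <- length(seqs)
  cov <- rep_len(cov, nf)
  protected <- rep_len(protected, nf)
  cp <- if (is.null(cov_plus)) rep(0, nf) else rep_len(as.numeric(cov_plus), nf)
  rc <- revcomp(seqs)
  pal <- rc == seqs
  seq_all <- c(seqs, rc[!pal])
  cov_all <- c(cov, cov[!pal])
  prot_all <- c(protected, protected[!pal])
  cp_all <- c(cp, rep(0, sum(!pal)))
  n <- length(seq_all)
  twin <- integer(n)
  twin[seq_len(nf)] <- ifelse(pal, seq_len(nf), nf + cumsum(!pal))
  twin[setdiff(seq_len(n), seq_len(nf))] <- which(!pal)
  cm_all <- numeric(n)
  cm_all[twin] <- cp_all                  # cov_minus(e) = cov_plus(twin(e))
  edges <- data.frame(
    from = substr(seq_all, 1L, k - 1L),
    to = substr(seq_all, nchar(seq_all) - k + 2L, nchar(seq_all)),
    seq = seq_all, cov = cov_all, cov_plus = cp_all, cov_minus = cm_all,
    twin = twin, self_rc = twin == seq_len(n), protected = prot_all,
    stringsAsFactors = FALSE
  )
  new_cdbg(k, edges)
}

# Remove edge rows (twins are pulled in automatically) and remap twin ids.
drop_edges <- function(g, idx) {
  if (length(idx) == 0) return(g)
  idx <- unique(c(idx, g$edges$twin[idx]))
  keep <- setdiff(seq_len(nrow(g$edges)), idx)
  e <- g$edges[keep, , drop = FALSE]
  e$twin <- match(g$edges$twin[keep], keep)
  pc <- if (!is.null(g$pcov_plus)) g$pcov_plus[keep] else NULL
  new_cdbg(g$k, e, pc)
}

# Re-contract maximal non-branching edge chains after removals. Preserves
# twin pairing, coverage mass, strand coverages and positional strand
# arrays; `protected` propagates if any merged unit was protected.
recondense <- function(g) {
  e <- g$edges
  n <- nrow(e)
  if (n == 0) return(g)
  k <- g$k
  verts <- unique(c(e$from, e$to))
  fid <- match(e$from, verts)
  tid <- match(e$to, verts)
  outdeg <- tabulate(fid, length(verts))
  indeg <- tabulate(tid, length(verts))
  out1 <- integer(length(verts)); out1[fid] <- seq_len(n)
  nxt <- ifelse(outdeg[tid] == 1L & indeg[tid] == 1L, out1[tid], NA_integer_)
  nxt[!is.na(nxt) & nxt == seq_len(n)] <- NA_integer_
  in1 <- integer(length(verts)); in1[tid] <- seq_len(n)
  prv <- ifelse(indeg[fid] == 1L & outdeg[fid] == 1L, in1[fid], NA_integer_)
  prv[!is.na(prv) & prv == seq_len(n)] <- NA_integer_
  if (all(is.na(nxt))) return(g)

  wk <- walk_chains(n, nxt, which(is.na(prv)))
  chains <- align_twin_cycles(wk$chains, wk$cycle, e$twin)
  m <- length(chains)
  nk <- nchar(e$seq) - k + 1L
  has_pc <- !is.null(g$pcov_plus)

  seqs <- character(m); from <- character(m); to <- character(m)
  cov <- numeric(m); cp <- numeric(m); cm <- numeric(m)
  prot <- logical(m)
  pc <- if (has_pc) vector("list", m) else NULL
  chain_of <- integer(n)
  last_of <- integer(m)
  for (i in seq_len(m)) {
    idx <- chains[[i]]
    chain_of[idx] <- i
    last_of[i] <- idx[length(idx)]
    if (length(idx) == 1L) {
      seqs[i] <- e$seq[idx]
    } else {
      seqs[i] <- paste0(e$seq[idx[1L]],
                        paste(substring(e$seq[idx[-1L]], k), collapse = ""))
    }
    w <- nk[idx]
    cov[i] <- sum(e$cov[idx] * w) / sum(w)
    cp[i] <- sum(e$cov_plus[idx] * w) / sum(w)
    cm[i] <- sum(e$cov_minus[idx] * w) / sum(w)
    prot[i] <- any(e$protected[idx])
    from[i] <- e$from[idx[1L]]
    to[i] <- e$to[idx[length(idx)]]
    if (has_pc) {
      pc[[i]] <- unlist(g$pcov_plus[idx], use.names = FALSE)
    }
  }
  twin <- chain_of[e$twin[last_of]]
  edges <- data.frame(
    from = from, to = to, seq = seqs, cov = cov, cov_plus = cp,
    cov_minus = cm, twin = twin, self_rc = twin == seq_len(m),
    protected = prot, stringsAsFactors = FALSE
  )
  new_cdbg(k, edges, pc)
}

# Internal invariant audit used by the test suite.
check_graph <- function(g) {
  e <- g$edges
  if (nrow(e) == 0) return(invisible(TRUE))
  stopifnot(
    all(e$twin %in% seq_len(nrow(e))),
    all(e$twin[e$twin] == seq_len(nrow(e))),
    all(e$self_rc == (e$twin == seq_len(nrow(e)))),
    all(abs(e$cov - e$cov[e$twin]) < 1e-9),
    all(nchar(e$seq) >= g$k),
    all(revcomp(e$seq) == e$seq[e$twin])
  )
  invisible(TRUE)
}

# data.table of unambiguous k-mer placements: kmer -> (edge row, 0-based pos).
edge_kmer_index <- function(g) {
  e <- g$edges
  if (nrow(e) == 0) {
    return(data.table::data.table(kmer = character(0), edge = integer(0),
                                  pos = integer(0), key = "kmer"))
  }
  k <- g$k
  nk <- edge_nk(g)
  lst <- lapply(seq_len(nrow(e)), function(i) {
    data.table::data.table(kmer = kmerize(e$seq[i], k), edge = i,
                           pos = seq_len(nk[i]) - 1L)
  })
  dt <- data.table::rbindlist(lst)
  dt <- dt[, if (.N == 1L) .SD, by = "kmer"]
  data.table::setkeyv(dt, "kmer")
  dt
}

# Total k-mer mass of the graph, counting each twin pair once.
graph_kmer_mass <- function(g) {
  e <- g$edges
  if (nrow(e) == 0) return(0)
  keep <- seq_len(nrow(e)) <= e$twin    # one row per pair (self_rc kept once)
  sum(e$cov[keep] * edge_nk(g)[keep])
}
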