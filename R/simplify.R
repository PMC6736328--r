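# RNA-specific graph cleaning. Every procedure removes an edge together
# with its twin, then re-condenses, so twin symmetry is preserved
# throughout. Tip clipping is deliberately conservative: transcript ends
# are legitimate tips, so removal needs low coverage, close similarity to
# an alternative edge, or poly-A/T low complexity.

# Positional adjacency index: integer vertex ids with O(1) incidence lists.
adjacency <- function(g) {
  e <- g$edges
  n <- nrow(e)
  verts <- unique(c(e$from, e$to))
  nv <- length(verts)
  fid <- match(e$from, verts)
  tid <- match(e$to, verts)
  list(
    nv = nv, fid = fid, tid = tid,
    outdeg = tabulate(fid, nv), indeg = tabulate(tid, nv),
    out = split(seq_len(n), factor(fid, levels = seq_len(nv))),
    inn = split(seq_len(n), factor(tid, levels = seq_len(nv)))
  )
}

#' Clip erroneous tips
#'
#' A tip is an edge with a dead-end (or, via its twin, dead-start) vertex
#' whose other endpoint attaches to the rest of the graph. A tip of length
#' l and mean k-mer coverage c_T is removed if any of:
#'
#' 1. `l < 2k` and `c_T <= 1` (short, very low coverage);
#' 2. `l < 4k`, `c_T < c_A / 2` and Hamming distance to the best-covered
#'    alternative edge at most 3 (sequencing-error tip; `c_A` is the
#'    alternative's coverage);
#' 3. more than 80% A/T content (poly-A low-complexity tip).
#'
#' The graph is re-condensed afterwards. Edges flagged `protected` are
#' exempt from the coverage-based rule 1.
#'
#' @param graph A `cdbg` object.
#' @param read_length Read length in bp (kept for interface symmetry with
#'   the other cleaners).
#' @param params [assembly_params()].
#' @return The cleaned, re-condensed graph.
#' @export
clip_tips <- function(graph, read_length, params = assembly_params()) {
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  k <- graph$k
  adj <- adjacency(graph)
  cand <- which(adj$outdeg[adj$tid] == 0L)      # dead-end edges
  drop <- integer(0)
  lens <- nchar(e$seq)
  for (i in cand) {
    v <- adj$fid[i]
    n_other <- adj$indeg[v] + adj$outdeg[v] - 1L
    if (n_other == 0L) next                     # isolated, not a tip
    l <- lens[i]; ct <- e$cov[i]
    if (!e$protected[i] &&
        l < params$tip_short_len_factor * k &&
        ct <= params$tip_short_cov_max) {
      drop <- c(drop, i); next
    }
    if (at_fraction(e$seq[i]) > params$tip_at_frac) {
      drop <- c(drop, i); next
    }
    alts <- setdiff(adj$out[[v]], c(i, e$twin[i]))
    if (length(alts) && l < params$tip_err_len_factor * k) {
      a <- alts[which.max(e$cov[alts])]
      if (ct < params$tip_err_cov_ratio * e$cov[a] &&
          hamming_prefix(e$seq[i], e$seq[a]) <= params$tip_err_hamming_max) {
        drop <- c(drop, i)
      }
    }
  }
  if (length(drop) == 0) return(graph)
  recondense(drop_edges(graph, drop))
}

#' Collapse error bulges
#'
#' A simple bulge is a pair of edges sharing both endpoints. Only bulges
#' whose edges have similar lengths (relative difference below 10%) are
#' collapsed -- exon-skipping isoforms produce parallel edges of clearly
#' different lengths and must survive. No coverage threshold is applied.
#' The higher-coverage edge is retained (ties broken by lexicographically
#' smaller sequence) and absorbs the removed edge's k-mer mass.
#'
#' @inheritParams clip_tips
#' @return The cleaned, re-condensed graph.
#' @export
collapse_bulges <- function(graph, params = assembly_params()) {
  repeat {
    r1 <- collapse_simple_bulges(graph, params)
    r2 <- collapse_path_bulges(r1$graph, params)
    graph <- r2$graph
    if (!r1$changed && !r2$changed) return(graph)
  }
}

# Pairwise case: two single edges sharing both endpoints.
collapse_simple_bulges <- function(graph, params) {
  changed_any <- FALSE
  repeat {
    e <- graph$edges
    n <- nrow(e)
    if (n == 0) break
    key <- paste(e$from, e$to, sep = "\r")
    multi <- key %in% key[duplicated(key)]
    grp <- split(which(multi), key[multi])
    if (length(grp) == 0) break
    removed <- logical(n)
    nk <- nchar(e$seq) - graph$k + 1L
    any_change <- FALSE
    for (idx in grp) {
      if (e$from[idx[1L]] == e$to[idx[1L]]) next      # self-loops
      repeat {
        live <- idx[!removed[idx]]
        if (length(live) < 2L) break
        hit <- FALSE
        prs <- utils::combn(live, 2L)
        for (ci in seq_len(ncol(prs))) {
          i <- prs[1L, ci]; j <- prs[2L, ci]
          if (e$twin[i] == j) next                    # hairpin pair
          l1 <- nchar(e$seq[i]); l2 <- nchar(e$seq[j])
          if (abs(l1 - l2) / max(l1, l2) >= params$bulge_len_diff_max) next
          keep <- if (e$cov[i] > e$cov[j]) i else if (e$cov[j] > e$cov[i]) j
            else if (e$seq[i] <= e$seq[j]) i else j
          lose <- if (keep == i) j else i
          add <- e$cov[lose] * nk[lose] / nk[keep]
          e$cov[keep] <- e$cov[keep] + add
          e$cov[e$twin[keep]] <- e$cov[keep]
          removed[c(lose, e$twin[lose])] <- TRUE
          hit <- TRUE; any_change <- TRUE
          break
        }
        if (!hit) break
      }
    }
    if (!any_change) break
    changed_any <- TRUE
    graph$edges <- e
    graph <- recondense(drop_edges(graph, which(removed)))
  }
  list(graph = graph, changed = changed_any)
}

# Generalised bulge: a single edge running parallel to a multi-edge path
# between the same vertices. Overlapping sequencing-error detours subdivide
# the correct side of a bulge into several edges, so the two-edge case
# alone cannot reach them. The same similar-length rule applies
# (< 10% difference); the single edge is removed only when its coverage
# does not exceed the alternative path's mean coverage, and its k-mer mass
# is projected onto the path.
collapse_path_bulges <- function(graph, params, max_len = 500L,
                                 max_states = 400L) {
  e <- graph$edges
  n <- nrow(e)
  if (n == 0) return(list(graph = graph, changed = FALSE))
  adj <- adjacency(graph)
  nk <- nchar(e$seq) - graph$k + 1L
  removed <- logical(n)
  cov <- e$cov
  for (a in seq_len(n)) {
    if (removed[a] || removed[e$twin[a]]) next
    if (e$from[a] == e$to[a]) next
    la <- nchar(e$seq[a])
    if (la > max_len) next
    if (adj$outdeg[adj$fid[a]] < 2L || adj$indeg[adj$tid[a]] < 2L) next
    lim <- ceiling(la * (1 + params$bulge_len_diff_max))
    # bounded DFS for an alternative path from(a) -> to(a) of similar length
    target <- adj$tid[a]
    stack <- list(list(v = adj$fid[a], len = 0L, edges = integer(0)))
    found <- NULL
    states <- 0L
    while (length(stack) && states < max_states) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      states <- states + 1L
      for (nx in adj$out[[st$v]]) {
        if (nx == a || removed[nx] || nx %in% st$edges) next
        nlen <- st$len + nk[nx]
        tot <- nlen + graph$k - 1L
        if (tot > lim) next
        if (adj$tid[nx] == target && length(st$edges) >= 1L &&
            abs(tot - la) / max(tot, la) < params$bulge_len_diff_max) {
          found <- c(st$edges, nx)
          break
        }
        stack[[length(stack) + 1L]] <-
          list(v = adj$tid[nx], len = nlen, edges = c(st$edges, nx))
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) next
    pcov <- sum(cov[found] * nk[found]) / sum(nk[found])
    if (cov[a] > pcov) next             # the single edge is the stronger side
    add <- cov[a] * nk[a] / sum(nk[found])
    cov[found] <- cov[found] + add
    cov[e$twin[found]] <- cov[found]
    removed[c(a, e$twin[a])] <- TRUE
  }
  if (!any(removed)) return(list(graph = graph, changed = FALSE))
  graph$edges$cov <- cov
  list(graph = recondense(drop_edges(graph, which(removed))), changed = TRUE)
}

#' Remove chimeric loops
#'
#' A chimeric loop is a self-loop edge hanging off the end of a correct
#' transcript edge: its vertex has total degree 3 (the loop counted twice
#' plus one long incident edge). Such loops arise from template-switching
#' junctions that connect a transcript end back into itself. Detection is
#' purely topological.
#'
#' @inheritParams clip_tips
#' @return The cleaned, re-condensed graph.
#' @export
remove_chimeric_loops <- function(graph, params = assembly_params()) {
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  adj <- adjacency(graph)
  loops <- which(e$from == e$to)
  drop <- integer(0)
  for (i in loops) {
    v <- adj$fid[i]
    others <- setdiff(c(adj$out[[v]], adj$inn[[v]]), i)
    if (length(others) != 1L) next
    if (nchar(e$seq[others]) <= params$chimeric_loop_min_adj_len * graph$k) next
    drop <- c(drop, i)
  }
  if (length(drop) == 0) return(graph)
  recondense(drop_edges(graph, drop))
}

#' Remove chimeric hairpins
#'
#' A hairpin edge connects a vertex to its own reverse-complement twin
#' vertex, joining a correct edge with its reverse-complement copy; its
#' twin edge then connects the same two vertices (a palindromic edge is its
#' own twin). Such edges are removed when the flanking vertex carries a
#' real adjacent edge, i.e. the hairpin hangs off genuine sequence.
#'
#' @inheritParams clip_tips
#' @return The cleaned, re-condensed graph.
#' @export
remove_hairpins <- function(graph, params = assembly_params()) {
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  adj <- adjacency(graph)
  hp <- which(e$from == e$from[e$twin] & e$to == e$to[e$twin] &
                e$from != e$to)
  drop <- integer(0)
  for (i in hp) {
    fam <- unique(c(i, e$twin[i]))
    ins <- setdiff(adj$inn[[adj$fid[i]]], fam)
    outs <- setdiff(adj$out[[adj$tid[i]]], fam)
    if (length(ins) + length(outs) == 0L) next    # isolated palindrome
    drop <- c(drop, i)
  }
  if (length(drop) == 0) return(graph)
  recondense(drop_edges(graph, drop))
}

#' Remove short low-coverage isolated edges
#'
#' An isolated edge has no adjacent edges at either endpoint. It is removed
#' when it has both low coverage (below 2) and length at most the read
#' length -- the signature of reads whose every k-mer contains an error, or
#' of trace contamination. Protected edges are exempt.
#'
#' @inheritParams clip_tips
#' @return The cleaned graph.
#' @export
remove_isolated_edges <- function(graph, read_length,
                                  params = assembly_params()) {
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  adj <- adjacency(graph)
  iso <- adj$indeg[adj$fid] == 0L & adj$outdeg[adj$tid] == 0L &
    adj$outdeg[adj$fid] == 1L & adj$indeg[adj$tid] == 1L
  drop <- which(iso & !e$protected &
                  e$cov < params$iso_edge_cov_max &
                  nchar(e$seq) <= read_length)
  if (length(drop) == 0) return(graph)
  drop_edges(graph, drop)
}

#' Split edges with opposing strand-specific coverage
#'
#' For stranded libraries, an edge formed by two opposite-strand transcripts
#' overlapping at their ends shows forward-dominated coverage on one side
#' and reverse-dominated coverage on the other. Such edges are cut at the
#' crossover into two detached edges, each dominated by one strand
#' (dominance = ratio of mean strand coverages at least
#' `strand_split_ratio`, with the dominant mean at least
#' `strand_split_min_cov`). Requires positional strand coverage from
#' [annotate_strand_coverage()].
#'
#' @inheritParams clip_tips
#' @return The graph with split edges detached.
#' @export
split_edges_by_strand <- function(graph, params = assembly_params()) {
  if (is.null(graph$pcov_plus)) {
    warning("no positional strand coverage available; returning graph unchanged")
    return(graph)
  }
  e <- graph$edges
  n <- nrow(e)
  done <- logical(n)
  cut_n <- 0L
  res_rows <- list()
  res_pc <- list()
  keep_rows <- integer(0)

  find_cut <- function(pp, pm) {
    nk <- length(pp)
    if (nk < 2L) return(NULL)
    cl_p <- cumsum(pp) / seq_len(nk)
    cl_m <- cumsum(pm) / seq_len(nk)
    cr_p <- rev(cumsum(rev(pp))) / rev(seq_len(nk))
    cr_m <- rev(cumsum(rev(pm))) / rev(seq_len(nk))
    best <- NULL; best_score <- 0
    r <- params$strand_split_ratio; mc <- params$strand_split_min_cov
    for (p in seq_len(nk - 1L)) {
      lp <- cl_p[p]; lm <- cl_m[p]; rp <- cr_p[p + 1L]; rm <- cr_m[p + 1L]
      a <- lp >= mc && rm >= mc && lp >= r * lm && rm >= r * rp
      b <- lm >= mc && rp >= mc && lm >= r * lp && rp >= r * rm
      if (a || b) {
        sc <- if (a) min(lp / max(lm, 1e-9), rm / max(rp, 1e-9)) else
          min(lm / max(lp, 1e-9), rp / max(rm, 1e-9))
        if (sc > best_score) { best <- p; best_score <- sc }
      }
    }
    best
  }

  for (i in seq_len(n)) {
    if (done[i]) next
    tw <- e$twin[i]
    done[c(i, tw)] <- TRUE
    keep_set <- if (tw == i) i else c(i, tw)
    pp <- graph$pcov_plus[[i]]
    pm <- if (tw == i) rev(pp) else rev(graph$pcov_plus[[tw]])
    if (is.null(pp) || is.null(pm) || length(pp) != length(pm)) {
      keep_rows <- c(keep_rows, keep_set); next
    }
    p <- find_cut(pp, pm)
    if (is.null(p)) { keep_rows <- c(keep_rows, keep_set); next }
    cut_n <- cut_n + 1L
    k <- graph$k
    s <- e$seq[i]
    nk <- length(pp)
    sl <- substr(s, 1L, p + k - 1L)
    sr <- substr(s, p + 1L, nchar(s))
    lab_a <- sprintf("%s|cut%dL", substr(s, p + 1L, p + k - 1L), cut_n)
    lab_b <- sprintf("%s|cut%dR", substr(s, p + 1L, p + k - 1L), cut_n)
    mk <- function(from, to, seqv, covv, cpv, cmv)
      data.frame(from = from, to = to, seq = seqv, cov = covv,
                 cov_plus = cpv, cov_minus = cmv, twin = NA_integer_,
                 self_rc = FALSE, protected = e$protected[i],
                 stringsAsFactors = FALSE)
    lp <- mean(pp[1:p]); lm <- mean(pm[1:p])
    rp <- mean(pp[(p + 1L):nk]); rm <- mean(pm[(p + 1L):nk])
    res_rows <- c(res_rows, list(
      mk(e$from[i], lab_a, sl, lp + lm, lp, lm),
      mk(revcomp(lab_a), revcomp(e$from[i]), revcomp(sl), lp + lm, lm, lp),
      mk(lab_b, e$to[i], sr, rp + rm, rp, rm),
      mk(revcomp(lab_b), revcomp(e$to[i]), revcomp(sr), rp + rm, rm, rp)
    ))
    res_pc <- c(res_pc,
                list(pp[1:p], rev(pm[1:p]),
                     pp[(p + 1L):nk], rev(pm[(p + 1L):nk])))
  }

  if (cut_n == 0L) return(graph)
  keep_rows <- unique(keep_rows)
  base <- graph$edges[keep_rows, , drop = FALSE]
  base$twin <- match(graph$edges$twin[keep_rows], keep_rows)
  base_pc <- graph$pcov_plus[keep_rows]
  extra <- do.call(rbind, res_rows)
  nb <- nrow(base)
  # appended rows come in consecutive (forward, reverse-complement) pairs
  extra$twin <- nb + seq_len(nrow(extra)) + rep(c(1L, -1L), nrow(extra) / 2L)
  edges <- rbind(base, extra)
  new_cdbg(graph$k, edges, c(base_pc, res_pc))
}

#' Iterate graph cleaning to a fixed point
#'
#' Applies tip clipping, bulge collapsing, chimeric-loop and hairpin
#' removal and isolated-edge filtering in order, re-condensing after each,
#' and repeats until no procedure changes the graph.
#'
#' @inheritParams clip_tips
#' @param max_rounds Safety cap on cleaning rounds.
#' @return The simplified graph.
#' @export
simplify_graph <- function(graph, read_length, params = assembly_params(),
                           max_rounds = 25L) {
  for (r in seq_len(max_rounds)) {
    sig <- graph_signature(graph)
    graph <- clip_tips(graph, read_length, params)
    graph <- collapse_bulges(graph, params)
    graph <- remove_chimeric_loops(graph, params)
    graph <- remove_hairpins(graph, params)
    graph <- remove_isolated_edges(graph, read_length, params)
    if (identical(graph_signature(graph), sig)) break
  }
  graph
}

graph_signature <- function(g) {
  if (nrow(g$edges) == 0) return("empty")
  paste(sort(paste0(g$edges$seq, ":", signif(g$edges$cov, 8))), collapse = ";")
}
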