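# Isoform reconstruction by path extension. Paths grow from the longest
# uncovered edge, extended by read-pair support; where pairs are silent and
# exactly two extensions compete, a coverage-based (or, for stranded data,
# strand-coverage-based) rule arbitrates. Multiple well-supported
# extensions fork the path, one copy per extension, so alternative
# isoforms are all reconstructed.

path_new <- function(edges, seed) list(edges = edges, seed = seed)

# Nucleotide sequence spelled by a path (edges overlap by k-1).
path_seq <- function(g, edges) {
  s <- g$edges$seq[edges]
  if (length(s) == 1L) return(s)
  paste0(s[1L], paste(substring(s[-1L], g$k), collapse = ""))
}

twin_path <- function(g, edges) rev(g$edges$twin[edges])

#' Score a candidate extension edge by read-pair support
#'
#' The score of candidate edge e relative to path P is the number of read
#' pairs with one mate anchored within one insert-size window of the end
#' of P (on a path edge, in path orientation) and the other mate anchored
#' on e in consistent orientation.
#'
#' @param graph A `cdbg` object.
#' @param path Integer vector of path edge ids.
#' @param candidate Edge id starting at the path's terminal vertex.
#' @param links A [map_read_pairs()] index.
#' @return Non-negative numeric score (a raw pair count).
#' @export
score_extension <- function(graph, path, candidate, links) {
  pr <- links$pairs
  if (is.null(pr) || nrow(pr) == 0) return(0)
  win <- links$insert_mean + 2 * links$insert_sd
  lens <- nchar(graph$edges$seq[path])
  # distance from the start of each path edge to the path end
  tail_at <- rev(cumsum(rev(lens - graph$k + 1L))) + graph$k - 1L
  keep <- which(tail_at <= win + lens)        # edges whose span reaches window
  sel <- pr[pr$e2 == candidate & pr$e1 %in% path[keep]]
  if (nrow(sel) == 0) return(0)
  dpos <- match(sel$e1, path)
  dist_to_end <- tail_at[dpos] - sel$off1
  length(unique(sel$id[dist_to_end >= 0 & dist_to_end <= win]))
}

#' Select all well-supported extensions
#'
#' Keeps every candidate whose score exceeds both the absolute threshold
#' theta and `max_score / C`; the path is then forked into one copy per
#' selected edge. The argmax candidate is always retained (C > 1).
#'
#' @param scores Numeric vector of candidate scores.
#' @param params [assembly_params()].
#' @return Integer indices of the selected candidates.
#' @export
select_extensions <- function(scores, params = assembly_params()) {
  if (length(scores) == 0) return(integer(0))
  m <- max(scores)
  which(scores > m / params$C & scores > params$theta)
}

# Shared logic of the coverage- and strand-based extenders. `covf` is the
# coverage accessor (total or forward-strand coverage).
coverage_arbitrate <- function(graph, path, cands, params, covf) {
  if (length(cands) != 2L) return(NA_integer_)
  e <- graph$edges
  adj <- adjacency(graph)
  m <- length(path)
  # vertices from the path end backwards, with the on-path incoming edge
  vs <- c(adj$tid[path[m]], adj$fid[path[m:2]])
  onp <- path[m:1]
  if (m == 1L) { vs <- adj$tid[path]; onp <- path }
  # last vertex on the path with an off-path incoming alternative
  alt <- NULL
  for (pi in seq_along(vs)) {
    ins <- adj$inn[[vs[pi]]]
    if (length(ins) < 2L) next
    if (!(onp[pi] %in% ins)) next
    offp <- setdiff(ins, onp[pi])
    if (length(offp) == 0L) next
    alt <- list(e2 = onp[pi], e2p = offp[which.max(covf(offp))])
    break
  }
  if (is.null(alt)) return(NA_integer_)
  c_ord <- cands[order(covf(cands), decreasing = TRUE)]
  ce <- c_ord[1L]; cep <- c_ord[2L]
  cov_e <- covf(ce); cov_ep <- covf(cep)
  cov_e2 <- covf(alt$e2); cov_e2p <- covf(alt$e2p)
  ok <- cov_e > params$delta * cov_ep &&
    cov_e2 > params$delta * cov_e2p &&
    cov_e > 0 && cov_e2 / cov_e < params$omega &&
    cov_e2 / cov_e > 1 / params$omega &&
    cov_e > params$C_min
  if (ok) ce else NA_integer_
}

#' Resolve a two-way extension by coverage depth
#'
#' Fallback used when the read-pair extender fails and the path has exactly
#' two possible extension edges e and e'. The most recent vertex with two
#' incoming alternatives -- one on the path (e2), one off it (e2') --
#' anchors the decision: extension e (the higher-covered candidate) is
#' returned iff cov(e) > delta * cov(e'), cov(e2) > delta * cov(e2'),
#' omega > cov(e2)/cov(e) > 1/omega, and cov(e) > C_min.
#'
#' @param graph A `cdbg` object.
#' @param path Integer vector of path edge ids.
#' @param cands Integer vector of candidate extension edge ids.
#' @param params [assembly_params()].
#' @return The selected edge id, or `NA` when the conditions fail.
#' @export
coverage_extend <- function(graph, path, cands, params = assembly_params()) {
  coverage_arbitrate(graph, path, cands, params,
                     function(i) graph$edges$cov[i])
}

#' Resolve a two-way extension by strand-specific coverage
#'
#' Identical rule to [coverage_extend()] but evaluated on the
#' library-forward strand coverage; used for stranded libraries, where
#' reverse-complement shadow edges have near-zero forward coverage and are
#' rejected by the C_min condition.
#'
#' @inheritParams coverage_extend
#' @param stranded Logical; `NA` is returned for unstranded data.
#' @return The selected edge id, or `NA`.
#' @export
strand_extend <- function(graph, path, cands, params = assembly_params(),
                          stranded = TRUE) {
  if (!stranded) return(NA_integer_)
  coverage_arbitrate(graph, path, cands, params,
                     function(i) graph$edges$cov_plus[i])
}

# Count appearances of an edge or its twin in a path.
edge_mult <- function(g, path, i) {
  sum(path == i | path == g$edges$twin[i])
}

# Grow a path forward until no extension passes; may fork. Returns a list
# of completed paths (edge id vectors).
grow_forward <- function(graph, links, start, params, stranded, adj) {
  work <- list(start)
  done <- list()
  while (length(work)) {
    p <- work[[1L]]; work[[1L]] <- NULL
    repeat {
      v <- adj$tid[p[length(p)]]
      cands <- adj$out[[v]]
      cands <- cands[vapply(cands, function(i)
        edge_mult(graph, p, i) < params$max_edge_multiplicity, logical(1))]
      if (stranded && length(cands) > 1L) {
        # reject candidates whose strand dominance opposes the path's:
        # reverse-complement shadow edges have near-zero forward coverage
        e <- graph$edges
        w <- nchar(e$seq[p]) - graph$k + 1L
        pp <- sum(e$cov_plus[p] * w); pm <- sum(e$cov_minus[p] * w)
        r <- params$strand_split_ratio
        keep <- if (pp > 2 * pm)
          !(e$cov_minus[cands] >= pmax(1, r * e$cov_plus[cands]))
        else if (pm > 2 * pp)
          !(e$cov_plus[cands] >= pmax(1, r * e$cov_minus[cands]))
        else rep(TRUE, length(cands))
        if (any(keep)) cands <- cands[keep]
      }
      if (length(cands) == 0L) { done[[length(done) + 1L]] <- p; break }
      scores <- vapply(cands, function(i)
        score_extension(graph, p, i, links), numeric(1))
      sel <- select_extensions(scores, params)
      if (length(sel) == 0L) {
        ce <- if (stranded)
          strand_extend(graph, p, cands, params, TRUE)
        else coverage_extend(graph, p, cands, params)
        if (is.na(ce)) { done[[length(done) + 1L]] <- p; break }
        p <- c(p, ce)
      } else if (length(sel) == 1L) {
        p <- c(p, cands[sel])
      } else {
        if (length(done) + length(work) + length(sel) >
            params$max_paths_per_seed) {
          sel <- sel[which.max(scores[sel])]
          p <- c(p, cands[sel])
        } else {
          for (s in sel[-1L]) work[[length(work) + 1L]] <- c(p, cands[s])
          p <- c(p, cands[sel[1L]])
        }
      }
    }
  }
  done
}

#' Reconstruct isoform paths covering the whole graph
#'
#' Seeds a path at the longest edge not yet included in any path (in either
#' orientation) and grows it in both directions: forward from the edge, and
#' backward by growing the twin path forward and splicing the result.
#' Read-pair multi-extension is tried first at every step; when it is
#' silent and exactly two extensions compete, the coverage (or, for
#' stranded data, strand-coverage) rule arbitrates. Repeats until every
#' edge is covered by at least one path.
#'
#' @param graph A simplified `cdbg` object.
#' @param links A [map_read_pairs()] index.
#' @param params [assembly_params()].
#' @param stranded Logical; selects the strand-coverage fallback.
#' @return List of paths, each a list with `edges` (ids) and `seed`.
#' @export
extend_all <- function(graph, links, params = assembly_params(),
                       stranded = FALSE) {
  e <- graph$edges
  if (nrow(e) == 0) return(list())
  adj <- adjacency(graph)
  covered <- logical(nrow(e))
  lens <- nchar(e$seq)
  paths <- list()
  repeat {
    free <- which(!covered)
    if (length(free) == 0) break
    seed <- free[which.max(lens[free])]
    fw <- grow_forward(graph, links, seed, params, stranded, adj)
    for (p in fw) {
      # grow the reverse direction from the twin path, then splice
      tp <- twin_path(graph, p)
      bw <- grow_forward(graph, links, tp, params, stranded, adj)
      for (q in bw) {
        full <- twin_path(graph, q)
        paths[[length(paths) + 1L]] <- path_new(full, seed)
        covered[full] <- TRUE
        covered[e$twin[full]] <- TRUE
      }
    }
  }
  paths
}

#' Drop duplicate and sub-paths
#'
#' A path is removed iff its edge list is identical to, or a contiguous
#' sublist of, another retained path's list; for unstranded data the
#' twin-reversed list is also compared. Nothing else is trimmed, so
#' isoforms differing by a single short exon both survive.
#'
#' @param paths List of paths from [extend_all()].
#' @param graph The `cdbg` the paths live in.
#' @param stranded Logical.
#' @return Filtered list of paths.
#' @export
remove_duplicate_paths <- function(paths, graph, stranded = FALSE) {
  if (length(paths) <= 1L) return(paths)
  n <- length(paths)
  lens <- vapply(paths, function(p) length(p$edges), integer(1))
  ord <- order(lens, decreasing = TRUE)
  keep <- logical(n)
  kept_keys <- character(0)
  key_of <- function(v) paste(v, collapse = ",")
  is_sub <- function(small, bigkeys) {
    ks <- key_of(small)
    any(vapply(bigkeys, function(b)
      grepl(paste0("(^|,)", ks, "(,|$)"), b, fixed = FALSE), logical(1)))
  }
  for (i in ord) {
    p <- paths[[i]]$edges
    dup <- is_sub(p, kept_keys)
    if (!dup && !stranded) {
      dup <- is_sub(twin_path(graph, p), kept_keys)
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_keys <- c(kept_keys, key_of(p))
    }
  }
  paths[keep]
}

#' Emit oriented contigs from paths
#'
#' For stranded data each path is emitted in the orientation with the
#' higher library-forward strand coverage (ties fall back to the canonical
#' choice); for unstranded data the canonical orientation (lexicographically
#' smaller of sequence and reverse complement) is emitted, making output
#' deterministic.
#'
#' @param paths List of paths.
#' @param graph The `cdbg` the paths live in.
#' @param stranded Logical.
#' @return A data.frame of contigs: `name`, `seq`, `length`, `cov`,
#'   `isolated` (single-edge path with no graph neighbours), `path` (comma
#'   separated edge ids).
#' @export
orient_paths <- function(paths, graph, stranded = FALSE) {
  e <- graph$edges
  if (length(paths) == 0) {
    return(data.frame(name = character(0), seq = character(0),
                      length = integer(0), cov = numeric(0),
                      isolated = logical(0), path = character(0),
                      stringsAsFactors = FALSE))
  }
  adj <- adjacency(graph)
  nk <- edge_nk(graph)
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]$edges
    s <- path_seq(graph, p)
    rc <- revcomp(s)
    use_fwd <- TRUE
    if (stranded) {
      w <- nk[p]
      cp_f <- sum(e$cov_plus[p] * w) / sum(w)
      tp <- twin_path(graph, p)
      cp_r <- sum(e$cov_plus[tp] * nk[tp]) / sum(nk[tp])
      use_fwd <- if (cp_f != cp_r) cp_f > cp_r else s <= rc
      if (!use_fwd) p <- tp
    } else {
      use_fwd <- s <= rc
      if (!use_fwd) p <- twin_path(graph, p)
    }
    sq <- if (use_fwd) s else rc
    w <- nk[p]
    iso <- length(p) == 1L &&
      adj$indeg[adj$fid[p]] == 0L && adj$outdeg[adj$tid[p]] == 0L &&
      adj$outdeg[adj$fid[p]] == 1L && adj$indeg[adj$tid[p]] == 1L
    data.frame(seq = sq, length = nchar(sq),
               cov = sum(e$cov[p] * w) / sum(w), isolated = iso,
               path = paste(p, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$length, out$seq), , drop = FALSE]
  out <- cbind(
    name = sprintf("NODE_%d_length_%d_cov_%.6g",
                   seq_len(nrow(out)), out$length, out$cov),
    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
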