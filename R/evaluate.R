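# Reference-based assembly scoring. Contigs are aligned to reference
# transcripts by exact k-mer chaining (k = 31 by default): hits on a common
# diagonal band form alignment segments, segments separated by a small gap
# are merged, and each contig's segments drive the completeness,
# duplication and misassembly metrics. This is deliberately lightweight --
# the synthetic data the package ships are near-exact -- and is not a
# general-purpose spliced aligner.

# Alignment segments of one contig against one reference sequence
# (forward orientation of the contig already chosen by the caller).
chain_hits <- function(cpos, rpos, k, band = 40L, max_gap = 1000L) {
  o <- order(cpos)
  cpos <- cpos[o]; rpos <- rpos[o]
  diag <- rpos - cpos
  segs <- list()
  start <- 1L
  n <- length(cpos)
  for (i in seq_len(n)) {
    brk <- i == n ||
      abs(diag[i + 1L] - diag[i]) > band ||
      (rpos[i + 1L] - rpos[i]) > max_gap ||
      rpos[i + 1L] < rpos[i]
    if (brk) {
      segs[[length(segs) + 1L]] <- list(
        c1 = cpos[start], c2 = cpos[i] + k - 1L,
        r1 = min(rpos[start:i]), r2 = max(rpos[start:i]) + k - 1L)
      start <- i + 1L
    }
  }
  segs
}

#' Evaluate an assembly against a reference transcriptome
#'
#' A reference transcript is X%-assembled iff at least X of its length is
#' covered by a single contig alignment. A contig is misassembled iff its
#' alignment decomposes into substantial segments from different reference
#' transcripts, or from distant (> 1 kb apart) or strand-discordant
#' positions of one transcript. Database coverage is the fraction of all
#' reference bases covered by any contig; duplication ratio is total
#' aligned contig bases over covered reference bases.
#'
#' @param contigs Character vector of contig sequences (or a contig
#'   data.frame from [orient_paths()] with a `seq` column).
#' @param reference Named character vector of reference transcripts.
#' @param thresholds Assembled-fraction thresholds to report.
#' @param k Alignment k-mer size.
#' @param min_seg Minimum segment length (bp) counted towards misassembly
#'   decomposition.
#' @return List of class `eval_report`: `n_transcripts`, `n_assembled` (per
#'   threshold), `database_coverage`, `duplication_ratio`,
#'   `n_misassemblies`, and per-reference best single-contig fractions.
#' @export
evaluate_assembly <- function(contigs, reference, thresholds = c(0.50, 0.95),
                              k = 31L, min_seg = 100L) {
  if (is.data.frame(contigs)) contigs <- contigs$seq
  stopifnot(length(reference) > 0)
  if (is.null(names(reference))) {
    names(reference) <- sprintf("ref%d", seq_along(reference))
  }
  nr <- length(reference)
  rlens <- nchar(reference)

  # reference k-mer index (forward strands; contigs are tried both ways)
  ref_dt <- data.table::rbindlist(lapply(seq_len(nr), function(i) {
    data.table::data.table(kmer = kmerize(reference[[i]], k), ref = i,
                           rpos = seq_len(max(rlens[i] - k + 1L, 0L)))
  }))
  if (nrow(ref_dt) == 0) stop("reference transcripts shorter than k")
  data.table::setkeyv(ref_dt, "kmer")

  best_frac <- numeric(nr)                       # per ref, best single contig
  cov_sets <- lapply(rlens, function(l) logical(l))
  aligned_contig_bases <- 0
  n_mis <- 0L
  n_unaligned <- 0L

  for (ci in seq_along(contigs)) {
    cseq <- contigs[[ci]]
    if (nchar(cseq) < k) { n_unaligned <- n_unaligned + 1L; next }
    hits_of <- function(s) {
      dt <- data.table::data.table(kmer = kmerize(s, k),
                                   cpos = seq_len(nchar(s) - k + 1L))
      ref_dt[dt, on = "kmer", nomatch = NULL]
    }
    h_f <- hits_of(cseq)
    h_r <- hits_of(revcomp(cseq))
    # orient the contig so the majority of hits are forward
    if (nrow(h_r) > nrow(h_f)) {
      cseq <- revcomp(cseq)
      tmp <- h_f; h_f <- h_r; h_r <- tmp
    }
    if (nrow(h_f) == 0) { n_unaligned <- n_unaligned + 1L; next }
    clen <- nchar(cseq)

    segs <- list()
    for (ri in unique(h_f$ref)) {
      hh <- h_f[h_f$ref == ri]
      for (s in chain_hits(hh$cpos, hh$rpos, k)) {
        s$ref <- ri; s$strand <- "+"
        segs[[length(segs) + 1L]] <- s
      }
    }
    # minority-strand segments indicate fold-backs: kept for the
    # misassembly decomposition only (coordinates mapped back onto the
    # forward contig)
    segs_o <- list()
    if (nrow(h_r)) {
      for (ri in unique(h_r$ref)) {
        hh <- h_r[h_r$ref == ri]
        for (s in chain_hits(hh$cpos, hh$rpos, k)) {
          c1 <- clen - s$c2 + 1L
          s$c2 <- clen - s$c1 + 1L
          s$c1 <- c1
          s$ref <- ri; s$strand <- "-"
          segs_o[[length(segs_o) + 1L]] <- s
        }
      }
    }

    # assign the contig to its best-matching reference: the one holding
    # the longest single alignment segment (an exon-skipping contig tiles
    # the longer isoform in two abutting segments but its own isoform in
    # one), ties broken by total aligned contig bases
    per_ref <- split(seq_along(segs), vapply(segs, `[[`, 0, "ref"))
    ref_cov <- lapply(per_ref, function(ix) {
      cc <- logical(nchar(cseq))
      for (si in ix) {
        s <- segs[[si]]
        cc[max(1L, s$c1):min(nchar(cseq), s$c2)] <- TRUE
      }
      sum(cc)
    })
    ref_maxseg <- vapply(per_ref, function(ix)
      max(vapply(segs[ix], function(s) s$c2 - s$c1 + 1L, numeric(1))),
      numeric(1))
    score <- ref_maxseg + unlist(ref_cov) / (nchar(cseq) + 1)
    best_rn <- names(per_ref)[which.max(score)]
    ri <- as.integer(best_rn)
    rc <- logical(rlens[ri])
    for (si in per_ref[[best_rn]]) {
      s <- segs[[si]]
      r1 <- max(1L, s$r1); r2 <- min(rlens[ri], s$r2)
      if (r2 >= r1) rc[r1:r2] <- TRUE
    }
    best_frac[ri] <- max(best_frac[ri], sum(rc) / rlens[ri])
    cov_sets[[ri]] <- cov_sets[[ri]] | rc
    aligned_contig_bases <- aligned_contig_bases + ref_cov[[best_rn]]

    # misassembly test: a clean contig is explained almost entirely by one
    # colinear chain of segments on a single reference and strand; a
    # fusion, fold-back or repeat-expansion contig is not
    all_segs <- c(segs, segs_o)
    ali_all <- logical(clen)
    for (s in all_segs) ali_all[max(1L, s$c1):min(clen, s$c2)] <- TRUE
    n_ali <- sum(ali_all)
    if (n_ali >= 2L * min_seg) {
      best_chain <- 0L
      grp_key <- vapply(all_segs, function(s) paste(s$ref, s$strand), "")
      for (gk in unique(grp_key)) {
        ss <- all_segs[grp_key == gk]
        ss <- ss[order(vapply(ss, `[[`, 0, "c1"))]
        strand <- ss[[1L]]$strand
        # DP over segments: best covered contig bases for a colinear chain
        ns <- length(ss)
        covlen <- vapply(ss, function(s) s$c2 - s$c1 + 1L, numeric(1))
        best <- covlen
        for (i in seq_len(ns)) {
          for (j in seq_len(i - 1L)) {
            a <- ss[[j]]; b <- ss[[i]]
            gap_c_ok <- b$c1 > a$c2 - 40L
            prog_ok <- if (strand == "+")
              b$r1 >= a$r2 - 40L && b$r1 - a$r2 <= 1000L
            else
              b$r2 <= a$r1 + 40L && a$r1 - b$r2 <= 1000L
            if (gap_c_ok && prog_ok) {
              cand <- best[j] + (b$c2 - max(b$c1, a$c2 + 1L) + 1L)
              if (cand > best[i]) best[i] <- cand
            }
          }
        }
        best_chain <- max(best_chain, max(best))
      }
      if (best_chain < 0.9 * n_ali) n_mis <- n_mis + 1L
    }
  }

  covered_ref_bases <- sum(vapply(cov_sets, sum, numeric(1)))
  n_assembled <- vapply(thresholds, function(th) sum(best_frac >= th),
                        integer(1))
  names(n_assembled) <- paste0("assembled_", thresholds * 100)
  structure(list(
    n_transcripts = length(contigs),
    n_reference = nr,
    n_assembled = n_assembled,
    database_coverage = covered_ref_bases / sum(rlens),
    duplication_ratio = if (covered_ref_bases > 0)
      aligned_contig_bases / covered_ref_bases else 0,
    n_misassemblies = n_mis,
    n_unaligned = n_unaligned,
    best_frac = stats::setNames(best_frac, names(reference))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("assembly evaluation\n")
  cat(sprintf("  contigs:            %d\n", x$n_transcripts))
  cat(sprintf("  reference seqs:     %d\n", x$n_reference))
  for (nm in names(x$n_assembled)) {
    cat(sprintf("  %s: %d\n", nm, x$n_assembled[[nm]]))
  }
  cat(sprintf("  database coverage:  %.1f%%\n", 100 * x$database_coverage))
  cat(sprintf("  duplication ratio:  %.3f\n", x$duplication_ratio))
  cat(sprintf("  misassemblies:      %d\n", x$n_misassemblies))
  invisible(x)
}
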