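k_fix <- 21L

# Branching fixture: trunk ending at a vertex from which an alternative
# edge and a tip both leave.
make_tip_graph <- function(tip_seq, tip_cov, alt_seq, alt_cov,
                           trunk_cov = 30) {
  v <- substr(alt_seq, 1, k_fix - 1L)
  trunk <- paste0(rdna(80), v)
  graph_from_edges(k_fix, c(trunk, alt_seq, tip_seq),
                   cov = c(trunk_cov, alt_cov, tip_cov))
}

test_that("short low-coverage tips are clipped, boundary cases retained", {
  set.seed(21)
  v <- rdna(k_fix - 1L)
  alt <- paste0(v, rdna(150))
  tip <- paste0(v, rdna(floor(1.5 * k_fix) - k_fix + 1L))   # l = 1.5k
  g <- make_tip_graph(tip, 1.0, alt, 30)
  g2 <- clip_tips(g, 100, assembly_params())
  expect_false(tip %in% g2$edges$seq)
  expect_true(any(grepl(alt, g2$edges$seq, fixed = TRUE)))

  # same tip at coverage just above the cutoff survives rule 1
  g3 <- clip_tips(make_tip_graph(tip, 1.01, alt, 1.8), 100, assembly_params())
  expect_true(tip %in% g3$edges$seq)
})

test_that("error tips go by similarity; four mismatches keep the tip", {
  set.seed(22)
  v <- rdna(k_fix - 1L)
  alt <- paste0(v, rdna(200))
  tip3 <- paste0(v, rnaforge:::mutate_positions(substr(alt, k_fix, 3 * k_fix),
                                                k_fix - 10 + (1:3)))
  tip4 <- paste0(v, rnaforge:::mutate_positions(substr(alt, k_fix, 3 * k_fix),
                                                k_fix - 10 + (1:4)))
  # l ~ 2k+2 < 4k, cov = 0.4 * c_A, Hamming 3 -> removed
  g <- clip_tips(make_tip_graph(tip3, 4, alt, 10), 100, assembly_params())
  expect_false(tip3 %in% g$edges$seq)
  # Hamming 4 -> retained
  g2 <- clip_tips(make_tip_graph(tip4, 4, alt, 10), 100, assembly_params())
  expect_true(tip4 %in% g2$edges$seq)
})

test_that("low-complexity A/T-rich tips are removed at any coverage", {
  set.seed(23)
  v <- rdna(k_fix - 1L)
  alt <- paste0(v, rdna(150))
  at_tail <- paste(sample(c("A", "T"), 100, TRUE), collapse = "")
  tip <- paste0(v, at_tail)
  stopifnot(rnaforge:::at_fraction(tip) > 0.8)
  g <- clip_tips(make_tip_graph(tip, 50, alt, 10), 100, assembly_params())
  expect_false(tip %in% g$edges$seq)
})

test_that("dissimilar alternative-terminal-exon tips both survive", {
  set.seed(24)
  shared <- rdna(260)
  exon_a <- rdna(80)
  exon_b <- rdna(80)
  tab <- count_kmers(c(rep(paste0(exon_a, shared), 20),
                       rep(paste0(exon_b, shared), 20)), k_fix)
  g <- simplify_graph(build_condensed_graph(tab), 100)
  seqs <- g$edges$seq
  expect_true(any(grepl(substr(exon_a, 1, 60), seqs, fixed = TRUE) |
                    grepl(revcomp(substr(exon_a, 1, 60)), seqs, fixed = TRUE)))
  expect_true(any(grepl(substr(exon_b, 1, 60), seqs, fixed = TRUE) |
                    grepl(revcomp(substr(exon_b, 1, 60)), seqs, fixed = TRUE)))
})

make_bulge_graph <- function(l1, l2, cov1, cov2) {
  v <- rdna(k_fix - 1L)
  w <- rdna(k_fix - 1L)
  e1 <- paste0(v, rdna(l1 - 2 * (k_fix - 1L)), w)
  e2 <- paste0(v, rdna(l2 - 2 * (k_fix - 1L)), w)
  list(g = graph_from_edges(k_fix, c(e1, e2), cov = c(cov1, cov2)),
       e1 = e1, e2 = e2)
}

test_that("bulges collapse only below the relative length bound", {
  set.seed(25)
  b <- make_bulge_graph(100, 105, 9, 3)        # 5% apart -> collapse
  g <- collapse_bulges(b$g, assembly_params())
  expect_equal(nrow(g$edges), 2L)
  expect_true(b$e1 %in% g$edges$seq)           # higher coverage retained
  # removed mass is projected onto the winner
  nk1 <- 100 - k_fix + 1; nk2 <- 105 - k_fix + 1
  expect_equal(g$edges$cov[g$edges$seq == b$e1], 9 + 3 * nk2 / nk1)

  b2 <- make_bulge_graph(100, 130, 9, 3)       # exon-inclusion scale: keep
  g2 <- collapse_bulges(b2$g, assembly_params())
  expect_equal(nrow(g2$edges), 4L)
})

test_that("equal-length equal-coverage bulges collapse deterministically", {
  set.seed(26)
  b <- make_bulge_graph(100, 100, 5, 5)
  g <- collapse_bulges(b$g, assembly_params())
  expect_equal(nrow(g$edges), 2L)
  expect_true(min(b$e1, b$e2) %in% g$edges$seq)
})

test_that("a parallel error detour collapses onto a subdivided correct path", {
  set.seed(27)
  # correct side split in two edges by an unrelated branch; detour is one
  # edge of almost the same total length
  v <- rdna(k_fix - 1L); m <- rdna(k_fix - 1L); w <- rdna(k_fix - 1L)
  p1 <- paste0(v, rdna(30), m)
  p2 <- paste0(m, rdna(30), w)
  stub <- paste0(m, rdna(40))                 # extra branch splitting the path
  detour <- paste0(v, rdna(nchar(p1) + nchar(p2) - 2 * (k_fix - 1) -
                             (k_fix - 1)), w)
  g <- graph_from_edges(k_fix, c(p1, p2, stub, detour), cov = c(20, 20, 5, 1))
  g2 <- collapse_bulges(g, assembly_params())
  expect_false(detour %in% g2$edges$seq)
  expect_true(any(grepl(substr(p1, k_fix, nchar(p1)), g2$edges$seq,
                        fixed = TRUE)))
})

test_that("chimeric self-loops at degree-3 vertices are removed", {
  set.seed(28)
  v <- rdna(k_fix - 1L)
  trunk <- paste0(rdna(80), v)                 # length > 2k
  loop <- paste0(v, rdna(30), v)
  g <- graph_from_edges(k_fix, c(trunk, loop), cov = c(20, 3))
  g2 <- remove_chimeric_loops(g, assembly_params())
  expect_false(loop %in% g2$edges$seq)
  expect_equal(nrow(g2$edges), 2L)

  # tandem-repeat loop at a through vertex (degree 4) is retained
  out <- paste0(v, rdna(80))
  g3 <- graph_from_edges(k_fix, c(trunk, loop, out), cov = c(20, 10, 20))
  g4 <- remove_chimeric_loops(g3, assembly_params())
  expect_true(loop %in% g4$edges$seq)

  # loop-free graph unchanged
  g5 <- graph_from_edges(k_fix, trunk)
  expect_identical(remove_chimeric_loops(g5)$edges$seq, g5$edges$seq)
})

test_that("hairpin edges joining a vertex to its twin are removed", {
  set.seed(29)
  v <- rdna(k_fix - 1L)
  e1 <- paste0(rdna(80), v)
  hp <- paste0(v, rdna(20), revcomp(v))
  g <- graph_from_edges(k_fix, c(e1, hp), cov = c(20, 2))
  g2 <- remove_hairpins(g, assembly_params())
  expect_false(hp %in% g2$edges$seq)
  expect_true(any(grepl(e1, g2$edges$seq, fixed = TRUE)))

  # inverted-repeat edge whose endpoints are not twins is retained
  u <- rdna(k_fix - 1L)
  inv <- paste0(u, rdna(20), revcomp(v))
  g3 <- graph_from_edges(k_fix, c(e1, paste0(rdna(80), u), inv),
                         cov = c(20, 20, 2))
  g4 <- remove_hairpins(g3, assembly_params())
  expect_true(inv %in% g4$edges$seq)
})

test_that("isolated-edge removal respects both printed conditions strictly", {
  set.seed(30)
  rl <- 100L
  mk <- function(len, cov) graph_from_edges(k_fix, rdna(len), cov = cov)
  expect_equal(nrow(remove_isolated_edges(mk(rl, 1.2), rl)$edges), 0L)
  expect_equal(nrow(remove_isolated_edges(mk(rl + 1L, 1.2), rl)$edges), 2L)
  expect_equal(nrow(remove_isolated_edges(mk(rl, 2.0), rl)$edges), 2L)
})

test_that("strand splitting cuts opposing-dominance edges and only those", {
  set.seed(31)
  s <- rdna(200)
  g <- graph_from_edges(k_fix, s)
  nk <- 200 - k_fix + 1L
  h <- nk %/% 2L
  plus_e <- c(rep(10, h), rep(0, nk - h))
  minus_e <- c(rep(0, h), rep(10, nk - h))
  g$pcov_plus <- list(plus_e, rev(minus_e))      # twin's forward = rev(minus)
  g2 <- split_edges_by_strand(g, assembly_params())
  expect_equal(nrow(g2$edges), 4L)
  rnaforge:::check_graph(g2)
  # detached: the cut vertex labels do not pair up across the two pieces
  adj <- rnaforge:::adjacency(g2)
  expect_true(all(adj$outdeg + adj$indeg[match(seq_len(adj$nv),
                                               seq_len(adj$nv))] <= 1))

  # uniformly forward-covered edge is untouched
  g3 <- graph_from_edges(k_fix, s)
  g3$pcov_plus <- list(rep(10, nk), rep(0, nk))
  expect_equal(nrow(split_edges_by_strand(g3, assembly_params())$edges), 2L)

  # dominance ratio 3 on each side is below the split threshold
  g4 <- graph_from_edges(k_fix, s)
  g4$pcov_plus <- list(c(rep(9, h), rep(3, nk - h)),
                       rev(c(rep(3, h), rep(9, nk - h))))
  expect_equal(nrow(split_edges_by_strand(g4, assembly_params())$edges), 2L)
})

test_that("simplification denoises an errorful transcript to the clean graph", {
  set.seed(32)
  t <- rdna(700)
  cfg0 <- sim_config(n_genes = 1, seed = 5, error_rate = 0, chimera_rate = 0,
                     mean_coverage = 25)
  truth <- data.frame(transcript_id = "t1", gene_id = "g1", structure = "1",
                      weight = 1)
  rd0 <- simulate_reads(c(t1 = t), truth, cfg0)
  cfg1 <- sim_config(n_genes = 1, seed = 5, error_rate = 0.005,
                     chimera_rate = 0, mean_coverage = 25)
  rd1 <- simulate_reads(c(t1 = t), truth, cfg1)
  clean <- simplify_graph(build_condensed_graph(
    count_kmers(c(rd0$r1, rd0$r2), k_fix)), 100)
  noisy <- simplify_graph(build_condensed_graph(
    count_kmers(c(rd1$r1, rd1$r2), k_fix)), 100)
  expect_equal(sort(clean$edges$seq), sort(noisy$edges$seq))
  expect_equal(nrow(clean$edges), 2L)
})

test_that("simplification is idempotent and never invents k-mers", {
  set.seed(33)
  for (rep in 1:3) {
    tab <- count_kmers(replicate(4, rdna(sample(100:250, 1))), k_fix)
    g0 <- build_condensed_graph(tab)
    g1 <- simplify_graph(g0, 100)
    g2 <- simplify_graph(g1, 100)
    expect_identical(rnaforge:::graph_signature(g1),
                     rnaforge:::graph_signature(g2))
    rnaforge:::check_graph(g1)
    k1 <- unlist(lapply(g1$edges$seq, rnaforge:::kmerize, k = k_fix))
    expect_true(all(canonical_kmer(k1) %in% names(tab$counts)))
  }
  # empty graph passes through
  ge <- build_condensed_graph(count_kmers(character(0), k_fix))
  expect_equal(nrow(simplify_graph(ge, 100)$edges), 0L)
})
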