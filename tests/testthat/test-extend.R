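# Fig-6a-style junction: e2 and e2' converge into a vertex, e3 continues,
# then e and e' diverge. Row order: forward seqs first (1..5), then
# reverse complements.
make_junction_graph <- function(covs, cov_plus = NULL) {
  v <- rdna(20); w <- rdna(20)
  seqs <- c(paste0(rdna(80), v),          # 1: e2 (on path)
            paste0(rdna(80), v),          # 2: e2' (alternative in-edge)
            paste0(v, rdna(60), w),       # 3: e3
            paste0(w, rdna(80)),          # 4: e  (extension)
            paste0(w, rdna(80)))          # 5: e' (competing extension)
  graph_from_edges(21, seqs, cov = covs, cov_plus = cov_plus)
}

empty_links <- structure(
  list(pairs = data.table::data.table(read = integer(0), e1 = integer(0),
                                      off1 = integer(0), n1 = integer(0),
                                      e2 = integer(0), off2 = integer(0),
                                      n2 = integer(0), id = integer(0)),
       insert_mean = 200, insert_sd = 20, read_length = 100L, n_mapped = 0L),
  class = "paired_links")

test_that("extension scores count supporting pairs in the insert window", {
  set.seed(61)
  g <- make_junction_graph(c(20, 5, 20, 20, 5))
  expect_equal(score_extension(g, c(1, 3), 4, empty_links), 0)
  links <- structure(list(
    pairs = data.table::data.table(read = 1:3, e1 = 3L, off1 = c(10L, 20L, 30L),
                                   n1 = 5L, e2 = 4L, off2 = 5L, n2 = 5L,
                                   id = 1:3),
    insert_mean = 200, insert_sd = 20, read_length = 100L, n_mapped = 3L),
    class = "paired_links")
  expect_equal(score_extension(g, c(1, 3), 4, links), 3)
  # a mate far beyond the insert window contributes nothing
  links$pairs$off1 <- -400L
  expect_equal(score_extension(g, c(1, 3), 4, links), 0)
})

test_that("the selection band keeps every score above max/C and theta", {
  p <- assembly_params()
  expect_equal(select_extensions(c(10, 8, 2), p), c(1L, 2L))
  expect_equal(select_extensions(5, p), 1L)
  expect_equal(select_extensions(c(1, 0.5), p), integer(0))  # all <= theta
  expect_equal(select_extensions(numeric(0), p), integer(0))
})

test_that("coverage arbitration enforces all four printed inequalities", {
  set.seed(62)
  p <- assembly_params()
  g <- make_junction_graph(c(20, 5, 20, 20, 5))
  expect_equal(coverage_extend(g, c(1, 3), c(4, 5), p), 4L)
  # condition i: extension fold-change 20/15 < delta
  g2 <- make_junction_graph(c(20, 5, 20, 20, 15))
  expect_true(is.na(coverage_extend(g2, c(1, 3), c(4, 5), p)))
  # condition ii: on-path alternative not dominant
  g3 <- make_junction_graph(c(20, 15, 20, 20, 5))
  expect_true(is.na(coverage_extend(g3, c(1, 3), c(4, 5), p)))
  # condition iii: coverage not persistent along the path (ratio > omega)
  g4 <- make_junction_graph(c(30, 5, 30, 2.5, 1))
  expect_true(is.na(coverage_extend(g4, c(1, 3), c(4, 5), p)))
  # condition iv: extension below C_min
  g5 <- make_junction_graph(c(3, 1, 3, 1.5, 0.5))
  expect_true(is.na(coverage_extend(g5, c(1, 3), c(4, 5), p)))
  # only applies to two-way forks
  expect_true(is.na(coverage_extend(g, c(1, 3), 4L, p)))
})

test_that("strand arbitration uses forward-strand coverage and needs strandedness", {
  set.seed(63)
  p <- assembly_params()
  # equal total coverage; forward coverage separates the candidates
  g <- make_junction_graph(c(20, 20, 40, 20, 20),
                           cov_plus = c(20, 0.5, 20, 20, 0.5))
  expect_equal(strand_extend(g, c(1, 3), c(4, 5), p, stranded = TRUE), 4L)
  expect_true(is.na(strand_extend(g, c(1, 3), c(4, 5), p, stranded = FALSE)))
  expect_true(is.na(coverage_extend(g, c(1, 3), c(4, 5), p)))
})

test_that("a linear graph yields a single path spelling the transcript", {
  set.seed(64)
  t <- rdna(600)
  g <- graph_from_edges(49, t, cov = 10)
  paths <- extend_all(g, empty_links, assembly_params())
  expect_length(paths, 1L)
  expect_equal(rnaforge:::path_seq(g, paths[[1]]$edges), g$edges$seq[
    paths[[1]]$edges])
})

test_that("both isoforms of a skipped-exon gene are reconstructed", {
  set.seed(65)
  cfg <- sim_config(n_genes = 1, seed = 20, error_rate = 0, chimera_rate = 0,
                    event_mix = c(skipped_exon = 1, alt_first = 0,
                                  alt_last = 0),
                    n_exons_range = c(4L, 4L), mean_coverage = 25)
  tx <- generate_transcriptome(cfg)
  rd <- simulate_reads(tx$transcripts, tx$truth, cfg)
  asm <- suppressMessages(assemble(rd$r1, rd$r2))
  ev <- evaluate_assembly(asm$normal, tx$transcripts)
  expect_equal(unname(ev$n_assembled[["assembled_95"]]), 2L)
  expect_equal(ev$n_misassemblies, 0L)
})

test_that("edge reuse in one path is capped", {
  set.seed(66)
  p <- assembly_params()
  v <- rdna(20)
  trunk_in <- paste0(rdna(80), v)
  loop <- paste0(v, rdna(40), v)
  trunk_out <- paste0(v, rdna(80))
  g <- graph_from_edges(21, c(trunk_in, loop, trunk_out), cov = c(10, 40, 10))
  # links that always support the loop
  links <- structure(list(
    pairs = data.table::data.table(read = 1:20, e1 = 2L,
                                   off1 = rep(1:20), n1 = 5L, e2 = 2L,
                                   off2 = 5L, n2 = 5L, id = 1:20),
    insert_mean = 200, insert_sd = 20, read_length = 100L, n_mapped = 20L),
    class = "paired_links")
  paths <- extend_all(g, links, p)
  mult <- vapply(paths, function(pp)
    sum(pp$edges == 2L | pp$edges == g$edges$twin[2L]), integer(1))
  expect_true(all(mult <= p$max_edge_multiplicity))
  # and every edge (or twin) is covered by some path
  used <- unique(unlist(lapply(paths, `[[`, "edges")))
  used <- unique(c(used, g$edges$twin[used]))
  expect_setequal(sort(used), seq_len(nrow(g$edges)))
})

test_that("duplicate and sub-paths are removed, reversals kept", {
  set.seed(67)
  g <- graph_from_edges(21, c(rdna(40), rdna(40), rdna(40)), cov = 5)
  mk <- function(v) list(edges = v, seed = v[1])
  out <- remove_duplicate_paths(list(mk(c(1, 2, 3)), mk(c(2, 3)), mk(c(1, 2, 3))),
                                g, stranded = TRUE)
  expect_length(out, 1L)
  out2 <- remove_duplicate_paths(list(mk(c(1, 2)), mk(c(2, 1))), g,
                                 stranded = TRUE)
  expect_length(out2, 2L)
  # unstranded: a twin-reversed copy is a duplicate
  tw <- g$edges$twin
  out3 <- remove_duplicate_paths(list(mk(c(1, 2)), mk(rev(tw[c(1, 2)]))), g,
                                 stranded = FALSE)
  expect_length(out3, 1L)
})

test_that("contig orientation is canonical unstranded and strand-led when stranded", {
  set.seed(68)
  s <- rdna(200)
  g <- graph_from_edges(21, s, cov = 5, cov_plus = 4.5)
  pth <- list(list(edges = 2L, seed = 2L))   # the reverse-complement row
  un <- orient_paths(pth, g, stranded = FALSE)
  expect_equal(un$seq, min(s, revcomp(s)))
  st <- orient_paths(pth, g, stranded = TRUE)
  expect_equal(st$seq, s)                    # forward strand carries cov_plus
  # strand tie falls back to the canonical orientation
  g$edges$cov_plus <- c(2, 2); g$edges$cov_minus <- c(2, 2)
  st2 <- orient_paths(pth, g, stranded = TRUE)
  expect_equal(st2$seq, min(s, revcomp(s)))
})
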