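test_that("k-mer sizes follow the read-length rules", {
  p <- select_kmer_sizes(100)
  expect_equal(p$k_low, 33L); expect_equal(p$k_high, 49L)
  expect_false(p$single_k)
  p <- select_kmer_sizes(150)
  expect_equal(p$k_low, 49L); expect_equal(p$k_high, 73L)
  p <- select_kmer_sizes(60)
  expect_true(p$single_k)
  expect_equal(p$k_high, 29L)
  expect_error(select_kmer_sizes(34), "at least 35")
})

test_that("k selection is odd, deterministic and monotone in read length", {
  rls <- seq(35, 250, by = 1)
  plans <- lapply(rls, select_kmer_sizes)
  kl <- vapply(plans, `[[`, 0L, "k_low")
  kh <- vapply(plans, `[[`, 0L, "k_high")
  expect_true(all(kl %% 2 == 1) && all(kh %% 2 == 1))
  expect_true(all(diff(kl) >= 0) && all(diff(kh) >= 0))
  single <- vapply(plans, `[[`, TRUE, "single_k")
  expect_true(all(kl >= 29 | single))
})

test_that("two-stage assembly bridges a low-coverage interior stretch", {
  set.seed(51)
  rl <- 100L
  t <- rdna(900)
  # dense flanks, interior sampled every 60 bp: consecutive reads share a
  # 33-mer (overlap 40) but not a 49-mer
  starts <- c(seq(1, 280, by = 3), seq(281, 620, by = 60), seq(621, 801, by = 3))
  reads <- tiled_pairs(t, starts, rl)
  plan2 <- select_kmer_sizes(rl)
  res2 <- two_stage_assemble(reads, plan2)
  single <- structure(list(k_low = 49L, k_high = 49L, single_k = TRUE),
                      class = "kplan")
  res1 <- two_stage_assemble(reads, single)
  expect_equal(max(nchar(res2$graph$edges$seq)), 900L)
  expect_lt(max(nchar(res1$graph$edges$seq)), 900L)
})

test_that("a clean high-coverage transcript assembles identically in both modes", {
  set.seed(52)
  t <- rdna(700)
  reads <- tiled_pairs(t, seq(1, 601, by = 3))
  res2 <- two_stage_assemble(reads, select_kmer_sizes(100))
  res1 <- two_stage_assemble(reads, structure(
    list(k_low = 49L, k_high = 49L, single_k = TRUE), class = "kplan"))
  expect_setequal(res2$graph$edges$seq, res1$graph$edges$seq)
  expect_true(t %in% res2$graph$edges$seq ||
                revcomp(t) %in% res2$graph$edges$seq)
})

test_that("near-terminal shared sequence does not produce a chimeric contig", {
  set.seed(53)
  sh <- rdna(45)                     # longer than k_low-1, shorter than k_high
  t1 <- paste0(rdna(400), sh, rdna(25))   # shared piece near the end of t1
  t2 <- paste0(rdna(25), sh, rdna(400))   # and near the start of t2
  reads <- list(
    r1 = c(tiled_pairs(t1, seq(1, 346, 3))$r1, tiled_pairs(t2, seq(1, 346, 3))$r1),
    r2 = c(tiled_pairs(t1, seq(1, 346, 3))$r2, tiled_pairs(t2, seq(1, 346, 3))$r2))
  res <- two_stage_assemble(reads, select_kmer_sizes(100))
  chimera <- paste0(substr(t1, 1, 445), substring(t2, 71))
  expect_false(any(vapply(res$graph$edges$seq, function(s)
    grepl(s, chimera, fixed = TRUE) && nchar(s) > 500, logical(1))))
  ev <- evaluate_assembly(res$graph$edges$seq[nchar(res$graph$edges$seq) > 150],
                          c(t1 = t1, t2 = t2))
  expect_equal(ev$n_misassemblies, 0L)
})

# A hand-built link index around two tips.
fake_links <- function(rows, insert_mean = 200, insert_sd = 20, rl = 100L) {
  dt <- data.table::as.data.table(rows)
  dt$read <- seq_len(nrow(dt)); dt$id <- dt$read
  dt$n1 <- 5L; dt$n2 <- 5L
  structure(list(pairs = dt, insert_mean = insert_mean, insert_sd = insert_sd,
                 read_length = rl, n_mapped = nrow(dt)),
            class = "paired_links")
}

two_tip_graph <- function(overlap) {
  a <- rdna(300)
  b <- paste0(substr(a, 301 - overlap, 300), rdna(300 - overlap))
  list(g = graph_from_edges(49, c(a, b), cov = 10), a = a, b = b)
}

test_that("tips glue on overlap plus one pair, or five pairs alone", {
  set.seed(54)
  tt <- two_tip_graph(10)
  # graph rows: 1 = a, 2 = b, 3 = rc(a), 4 = rc(b)
  links1 <- fake_links(data.frame(e1 = 1, off1 = 250, e2 = 2, off2 = 10))
  g <- close_gaps(tt$g, links1, assembly_params())
  expect_equal(nrow(g$edges), 2L)
  expect_true(paste0(tt$a, substring(tt$b, 11)) %in% g$edges$seq)

  # no sequence overlap: five spanning pairs required
  set.seed(55)
  tt2 <- two_tip_graph(0)
  mk <- function(n) fake_links(data.frame(e1 = rep(1, n),
                                          off1 = 240 + seq_len(n),
                                          e2 = rep(2, n), off2 = seq_len(n)))
  expect_equal(nrow(close_gaps(tt2$g, mk(4), assembly_params())$edges), 4L)
  g5 <- close_gaps(tt2$g, mk(5), assembly_params())
  expect_equal(nrow(g5$edges), 2L)

  # overlap but zero spanning pairs: not glued
  set.seed(56)
  tt3 <- two_tip_graph(10)
  links0 <- fake_links(data.frame(e1 = integer(0), off1 = integer(0),
                                  e2 = integer(0), off2 = integer(0)))
  expect_equal(nrow(close_gaps(tt3$g, links0, assembly_params())$edges), 4L)
})

test_that("gap closing never joins a tip to its own twin", {
  set.seed(57)
  a <- rdna(300)
  g <- graph_from_edges(49, a, cov = 10)
  links <- fake_links(data.frame(e1 = rep(1, 6), off1 = 250 + seq_len(6),
                                 e2 = rep(2, 6), off2 = seq_len(6)))  # 2 = twin
  expect_equal(nrow(close_gaps(g, links, assembly_params())$edges), 2L)
})

test_that("a tip with several eligible partners stays unglued", {
  set.seed(58)
  a <- rdna(300); b <- rdna(300); c <- rdna(300)
  g <- graph_from_edges(49, c(a, b, c), cov = 10)
  # rows: 1=a 2=b 3=c 4=rc(a) 5=rc(b) 6=rc(c); a connects to both b and c
  rows <- data.frame(e1 = rep(1, 10), off1 = 245 + rep(1:5, 2),
                     e2 = c(rep(2, 5), rep(3, 5)), off2 = rep(1:5, 2))
  g2 <- close_gaps(g, fake_links(rows), assembly_params())
  expect_equal(nrow(g2$edges), 6L)
})

test_that("an interior coverage hole is closed into a single contig", {
  set.seed(59)
  t <- rdna(700)
  rl <- 100L
  # left block covers [1..360], right block covers [352..700]: the tip
  # sequences share a 9 bp exact overlap but no 49-mer
  sl <- seq(1, 241, by = 4)
  sr <- seq(352, 601, by = 4)
  r1 <- c(substring(t, sl, sl + rl - 1), substring(t, sr, sr + rl - 1))
  r2 <- c(revcomp(substring(t, sl + 20, sl + 119)),
          revcomp(substring(t, sr + 20, sr + 119)))
  # spanning pairs across the hole
  sp <- seq(230, 262, by = 8)
  r1 <- c(r1, substring(t, sp, sp + rl - 1))
  r2 <- c(r2, revcomp(substring(t, sp + 200, sp + 299)))
  ok <- nchar(r1) == rl & nchar(r2) == rl
  res <- two_stage_assemble(list(r1 = r1[ok], r2 = r2[ok]),
                            select_kmer_sizes(rl))
  expect_equal(nrow(res$graph$edges), 2L)
  expect_gte(max(nchar(res$graph$edges$seq)), 690L)
})
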