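# Ground-truthed transcriptome and read simulator. Generates gene models
# with alternative-splicing structure (skipped exons, alternative first and
# last exons), optional diverged paralogs, log-normal expression, poly-A
# tails, paired-end reads with substitution errors under unstranded or
# RF/FR stranded protocols, and injected chimeric read pairs of the
# loop (same-strand back-jump) and hairpin (exact fold-back) classes.

#' Simulation configuration
#'
#' All knobs of the transcriptome/read generator. Defaults describe the
#' package's reference simulation: 50 two-isoform genes with skipped-exon
#' events longer than any assembly k, 20x mean coverage of 2 x 100 bp
#' pairs, 0.5% substitution errors and 1% chimeric pairs.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene 1 or 2 isoforms per gene.
#' @param event_mix Named probabilities for the second isoform's event type
#'   (`skipped_exon`, `alt_first`, `alt_last`).
#' @param n_exons_range Range of exon counts per gene.
#' @param exon_len_range Range of exon lengths (bp); the minimum should
#'   exceed the assembly k so isoform bulges are structurally distinct.
#' @param paralog_rate Probability that a gene spawns a diverged paralog.
#' @param paralog_divergence Per-base substitution rate of paralogs.
#' @param expr_meanlog,expr_sdlog Log-normal expression weight parameters.
#' @param read_length Read length (bp).
#' @param insert_mean,insert_sd Fragment (insert) size distribution.
#' @param error_rate Per-base substitution error rate of reads.
#' @param strandedness `"none"`, `"RF"` or `"FR"`.
#' @param mean_coverage Target mean read coverage over transcript bases.
#' @param chimera_rate Fraction of read pairs replaced by chimeras.
#' @param chimera_mix Named probabilities for chimera classes (`loop`,
#'   `hairpin`).
#' @param polya_len Poly-A tail length appended to every transcript.
#' @param seed Mandatory RNG seed; every stochastic call flows through it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       isoforms_per_gene = 2L,
                       event_mix = c(skipped_exon = 0.5, alt_first = 0.25,
                                     alt_last = 0.25),
                       n_exons_range = c(3L, 6L),
                       exon_len_range = c(80L, 250L),
                       paralog_rate = 0,
                       paralog_divergence = 0.02,
                       expr_meanlog = 0,
                       expr_sdlog = 0.5,
                       read_length = 100L,
                       insert_mean = 200,
                       insert_sd = 20,
                       error_rate = 0.005,
                       strandedness = c("none", "RF", "FR"),
                       mean_coverage = 20,
                       chimera_rate = 0.01,
                       chimera_mix = c(loop = 0.2, hairpin = 0.8),
                       polya_len = 15L,
                       seed) {
  strandedness <- match.arg(strandedness)
  if (missing(seed) || is.na(seed)) stop("a seed is mandatory")
  stopifnot(
    n_genes >= 1, isoforms_per_gene %in% c(1L, 2L),
    all(exon_len_range >= 1), all(n_exons_range >= 1),
    paralog_rate >= 0, paralog_rate <= 1,
    error_rate >= 0, error_rate <= 1,
    chimera_rate >= 0, chimera_rate <= 1,
    polya_len >= 0
  )
  structure(list(
    n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    event_mix = event_mix / sum(event_mix),
    n_exons_range = as.integer(n_exons_range),
    exon_len_range = as.integer(exon_len_range),
    paralog_rate = paralog_rate,
    paralog_divergence = paralog_divergence,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    error_rate = error_rate,
    strandedness = strandedness,
    mean_coverage = mean_coverage,
    chimera_rate = chimera_rate,
    chimera_mix = chimera_mix / sum(chimera_mix),
    polya_len = as.integer(polya_len),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a ground-truthed transcriptome
#'
#' Builds gene models exon by exon and emits one or two isoforms per gene:
#' the full exon chain plus, optionally, a variant created by a skipped
#' internal exon, an alternative first exon or an alternative last exon.
#' Paralogs are diverged copies of a whole gene. A poly-A tail is appended
#' to every transcript. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (named character vector) and `truth`
#'   (data.frame: `transcript_id`, `gene_id`, `structure`, `weight`).
#' @export
generate_transcriptome <- function(config) {
  set.seed(config$seed)
  transcripts <- character(0)
  truth <- list()
  polya <- strrep("A", config$polya_len)
  emit <- function(tid, gid, structure, exons, idxs) {
    seq <- paste0(paste(exons[idxs], collapse = ""), polya)
    transcripts[[tid]] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, structure = structure,
      weight = stats::rlnorm(1, config$expr_meanlog, config$expr_sdlog),
      stringsAsFactors = FALSE)
  }
  make_gene <- function(gid) {
    ne <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]), 1)
    exons <- vapply(seq_len(ne), function(i)
      random_dna(sample(seq(config$exon_len_range[1],
                            config$exon_len_range[2]), 1)), character(1))
    emit(paste0(gid, ".1"), gid, paste(seq_len(ne), collapse = "-"),
         exons, seq_len(ne))
    if (config$isoforms_per_gene == 2L) {
      ev <- sample(names(config$event_mix), 1, prob = config$event_mix)
      if (ev == "skipped_exon" && ne >= 3L) {
        skip <- if (ne == 3L) 2L else sample(2:(ne - 1L), 1)
        emit(paste0(gid, ".2"), gid,
             paste(setdiff(seq_len(ne), skip), collapse = "-"),
             exons, setdiff(seq_len(ne), skip))
      } else if (ev == "alt_first" || ne < 3L) {
        alt <- random_dna(sample(seq(config$exon_len_range[1],
                                     config$exon_len_range[2]), 1))
        exons2 <- c(alt, exons[-1L])
        emit(paste0(gid, ".2"), gid,
             paste(c("1a", seq_len(ne)[-1L]), collapse = "-"),
             exons2, seq_len(ne))
      } else {
        alt <- random_dna(sample(seq(config$exon_len_range[1],
                                     config$exon_len_range[2]), 1))
        exons2 <- c(exons[-ne], alt)
        emit(paste0(gid, ".2"), gid,
             paste(c(seq_len(ne)[-ne], paste0(ne, "a")), collapse = "-"),
             exons2, seq_len(ne))
      }
    }
    exons
  }
  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("gene%03d", gi)
    exons <- make_gene(gid)
    if (stats::runif(1) < config$paralog_rate) {
      pid <- paste0(gid, "p")
      ne <- length(exons)
      div <- lapply(exons, function(x) {
        npos <- stats::rbinom(1, nchar(x), config$paralog_divergence)
        mutate_positions(x, sample(nchar(x), npos))
      })
      emit(paste0(pid, ".1"), pid, paste(seq_len(ne), collapse = "-"),
           unlist(div), seq_len(ne))
    }
  }
  list(transcripts = unlist(transcripts),
       truth = do.call(rbind, truth))
}

# Draw mates from a sense fragment under the configured protocol.
fragment_to_pair <- function(frag, rl, protocol, flip) {
  L <- nchar(frag)
  m_left <- substr(frag, 1L, rl)
  m_right <- revcomp(substr(frag, L - rl + 1L, L))
  if (protocol == "RF") list(r1 = m_right, r2 = m_left)
  else if (protocol == "FR") list(r1 = m_left, r2 = m_right)
  else if (flip) list(r1 = m_right, r2 = m_left)   # unstranded: either strand
  else list(r1 = m_left, r2 = m_right)
}

#' Simulate paired-end reads
#'
#' Fragment counts per transcript are proportional to expression weight
#' times length, totalling the configured mean coverage; fragment
#' positions are uniform, insert sizes normal, mates are taken from the
#' fragment ends. Orientation follows the protocol: FR emits the first
#' mate on the transcript strand, RF emits it antisense; unstranded pairs
#' come from either strand with equal probability. Substitution errors are
#' i.i.d. per base. Deterministic given the config seed.
#'
#' @param transcripts Named character vector from [generate_transcriptome()].
#' @param truth Truth table from the same call.
#' @param config A [sim_config()].
#' @return List of class `sim_reads`: `r1`, `r2` (character vectors),
#'   `origin` (transcript id per pair), `chimeric` (logical per pair).
#' @export
simulate_reads <- function(transcripts, truth, config) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  lens <- nchar(transcripts)
  w <- truth$weight[match(names(transcripts), truth$transcript_id)]
  min_len <- config$insert_mean - 3 * config$insert_sd
  usable <- lens >= min_len
  if (any(!usable)) {
    warning(sprintf("%d transcript(s) shorter than insert_mean - 3 sd skipped",
                    sum(!usable)))
  }
  n_total <- round(config$mean_coverage * sum(lens[usable]) / (2 * rl))
  share <- w[usable] * lens[usable]
  n_t <- round(n_total * share / sum(share))
  ids <- rep(names(transcripts)[usable], n_t)
  n <- length(ids)
  if (n == 0) {
    return(structure(list(r1 = character(0), r2 = character(0),
                          origin = character(0), chimeric = logical(0)),
                     class = "sim_reads"))
  }
  tl <- lens[ids]
  ins <- pmin(pmax(round(stats::rnorm(n, config$insert_mean,
                                      config$insert_sd)), rl + 10L), tl)
  # fragment placements may overhang the transcript boundaries and are
  # clipped (terminal fragments are shorter, never absent), keeping
  # per-base coverage roughly uniform out to the transcript ends
  minfrag <- rl
  start0 <- floor(stats::runif(n) * (tl + ins - 2L * minfrag + 1L)) +
    1L - (ins - minfrag)
  fs <- pmax(1L, start0)
  fe <- pmin(tl, start0 + ins - 1L)
  frags <- substring(transcripts[ids], fs, fe)
  flips <- stats::runif(n) < 0.5
  proto <- config$strandedness
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    p <- fragment_to_pair(frags[i], rl,
                          if (proto == "none") "none" else proto, flips[i])
    r1[i] <- p$r1; r2[i] <- p$r2
  }
  add_errors <- function(reads) {
    ne <- stats::rbinom(length(reads), nchar(reads), config$error_rate)
    hit <- which(ne > 0)
    for (i in hit) {
      reads[i] <- mutate_positions(reads[i], sample(nchar(reads[i]), ne[i]))
    }
    reads
  }
  if (config$error_rate > 0) {
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)
  }
  structure(list(r1 = r1, r2 = r2, origin = ids,
                 chimeric = logical(n)),
            class = "sim_reads")
}

#' Inject chimeric read pairs
#'
#' Replaces a configured fraction of pairs with template-switching
#' artefacts arising during reverse transcription of the pair's own
#' template. Two classes are modelled: loop chimeras, where the
#' polymerase slips a short distance back from the transcript's 3' end
#' and re-copies the terminal segment (a rolling repeat whose junction
#' forms a self-loop in the assembly graph), and hairpin chimeras, where
#' the template folds back exactly onto the opposite strand, producing a
#' palindromic junction. Fold-backs are the commoner class. Injected pair
#' indices are recorded in the `chimeric` flag.
#'
#' @param reads A [simulate_reads()] result.
#' @param transcripts Named character vector of transcript sequences.
#' @param config A [sim_config()].
#' @return The modified `sim_reads` object.
#' @export
inject_chimeras <- function(reads, transcripts, config) {
  if (config$chimera_rate <= 0 || length(reads$r1) == 0) return(reads)
  set.seed(config$seed + 2L)
  rl <- config$read_length
  n <- length(reads$r1)
  pick <- which(stats::runif(n) < config$chimera_rate)
  if (length(pick) == 0) return(reads)
  half <- max(rl, ceiling(config$insert_mean / 2))
  for (i in pick) {
    tid <- reads$origin[i]
    tseq <- transcripts[[tid]]
    L <- nchar(tseq)
    if (L < half + 80L) next                   # template too short to slip
    type <- sample(names(config$chimera_mix), 1, prob = config$chimera_mix)
    if (type == "loop") {
      # terminal slippage: jump a short distance back from the 3' end and
      # re-copy the terminal segment until the fragment is long enough
      back <- sample(20:60, 1)
      unit <- substr(tseq, L - back + 1L, L)
      s <- paste0(substr(tseq, L - half + 1L, L),
                  strrep(unit, ceiling(half / back)))
      s <- substr(s, 1L, half + half)
    } else {
      # exact fold-back onto the opposite strand at position j
      j <- sample(seq(half + 1L, L), 1)
      s <- paste0(substr(tseq, j - half + 1L, j),
                  revcomp(substr(tseq, j - half + 1L, j)))
    }
    # centre the first mate on the (first) junction so its k-mers span it
    js <- half
    a <- max(1L, js - rl %/% 2L)
    m1 <- substr(s, a, a + rl - 1L)
    m2 <- revcomp(substr(s, max(1L, nchar(s) - rl + 1L), nchar(s)))
    reads$r1[i] <- m1
    reads$r2[i] <- m2
    reads$chimeric[i] <- TRUE
  }
  reads
}
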