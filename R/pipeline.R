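#' Assemble a transcriptome from paired-end reads
#'
#' End-to-end driver: selects k-mer sizes from the read length, runs the
#' two-pass graph construction with RNA-specific simplification and gap
#' closing, reconstructs isoform paths with the multi-extension rule (plus
#' coverage/strand fallbacks), deduplicates and orients them, and applies
#' the three filtration presets.
#'
#' @param r1,r2 Character vectors of mate sequences, or FASTQ paths.
#' @param protocol `"unstranded"`, `"RF"` or `"FR"`.
#' @param k `"auto"` (from read length), a single odd integer, or a vector
#'   of two odd integers `c(k_low, k_high)`.
#' @param params [assembly_params()].
#' @param outdir Optional output directory; when given, writes
#'   `transcripts_soft.fasta`, `transcripts.fasta`, `transcripts_hard.fasta`,
#'   `assembly_graph.gfa` and `params.yaml`.
#' @param save_graphs Also dump the pre-simplification graph (debugging).
#' @return List of class `rnaforge_assembly`: `graph`, `contigs` (all,
#'   unfiltered), `soft`, `normal`, `hard` (filtered contig data.frames),
#'   `plan`, `read_length`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 2, seed = 7, chimera_rate = 0)
#' tx <- generate_transcriptome(cfg)
#' rd <- simulate_reads(tx$transcripts, tx$truth, cfg)
#' asm <- assemble(rd$r1, rd$r2)
#' nrow(asm$normal)
assemble <- function(r1, r2, protocol = c("unstranded", "RF", "FR"),
                     k = "auto", params = assembly_params(),
                     outdir = NULL, save_graphs = FALSE) {
  protocol <- match.arg(protocol)
  if (length(r1) == 1 && file.exists(r1)) r1 <- read_fastq(r1)
  if (length(r2) == 1 && file.exists(r2)) r2 <- read_fastq(r2)
  if (length(r1) != length(r2)) stop("r1 and r2 must pair up")
  reads <- list(r1 = unname(toupper(r1)), r2 = unname(toupper(r2)))
  rl <- if (length(reads$r1))
    as.integer(stats::median(nchar(c(reads$r1, reads$r2)))) else 0L

  plan <- resolve_kplan(k, rl)
  message(sprintf("[rnaforge] %d read pairs, read length %d, %s", length(r1),
                  rl, format(plan)))
  res <- two_stage_assemble(reads, plan, params, protocol,
                            keep_raw = save_graphs)
  g <- res$graph
  message(sprintf("[rnaforge] final graph: %d edges", nrow(g$edges)))
  stranded <- protocol %in% c("RF", "FR")
  paths <- extend_all(g, res$links, params, stranded)
  paths <- remove_duplicate_paths(paths, g, stranded)
  contigs <- orient_paths(paths, g, stranded)
  message(sprintf("[rnaforge] %d paths -> %d contigs", length(paths),
                  nrow(contigs)))
  out <- list(
    graph = g,
    contigs = contigs,
    soft = filter_transcripts(contigs, "soft", rl),
    normal = filter_transcripts(contigs, "normal", rl),
    hard = filter_transcripts(contigs, "hard", rl),
    plan = plan,
    read_length = rl
  )
  class(out) <- "rnaforge_assembly"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$soft, file.path(outdir, "transcripts_soft.fasta"))
    write_fasta(out$normal, file.path(outdir, "transcripts.fasta"))
    write_fasta(out$hard, file.path(outdir, "transcripts_hard.fasta"))
    write_gfa(g, file.path(outdir, "assembly_graph.gfa"))
    if (save_graphs && !is.null(res$raw_graph)) {
      write_gfa(res$raw_graph,
                file.path(outdir, "assembly_graph_raw.gfa"))
    }
    write_params(params, file.path(outdir, "params.yaml"))
  }
  out
}

format.kplan <- function(x, ...) {
  if (x$single_k) sprintf("single k = %d", x$k_high)
  else sprintf("k = %d,%d", x$k_low, x$k_high)
}

resolve_kplan <- function(k, read_length) {
  if (identical(k, "auto")) return(select_kmer_sizes(read_length))
  k <- as.integer(k)
  if (any(is.na(k)) || any(k %% 2L == 0L)) {
    stop("k must be 'auto', one odd integer, or two odd integers")
  }
  if (length(k) == 1L) {
    structure(list(k_low = k, k_high = k, single_k = TRUE), class = "kplan")
  } else if (length(k) == 2L) {
    k <- sort(k)
    structure(list(k_low = k[1L], k_high = k[2L], single_k = k[1L] == k[2L]),
              class = "kplan")
  } else stop("k must have length 1 or 2")
}

#' @export
print.rnaforge_assembly <- function(x, ...) {
  cat(sprintf("rnaforge assembly (%s)\n", format(x$plan)))
  cat(sprintf("  graph edges:   %d\n", nrow(x$graph$edges)))
  cat(sprintf("  contigs:       %d (soft %d / normal %d / hard %d)\n",
              nrow(x$contigs), nrow(x$soft), nrow(x$normal), nrow(x$hard)))
  invisible(x)
}
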