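#' Assembly parameters
#'
#' Bundles every tunable constant of the assembler: tip-clipping thresholds,
#' bulge and isolated-edge rules, gap-closing support counts, path-extension
#' scoring constants and the strand-splitting dominance ratio. Defaults are
#' the method's standard values; see the methods vignette for the rationale
#' behind each.
#'
#' @param tip_short_len_factor Tips shorter than this multiple of k are
#'   candidates for the low-coverage rule.
#' @param tip_short_cov_max Maximum mean k-mer coverage for the short-tip
#'   rule (`l < tip_short_len_factor * k` and `cov <= tip_short_cov_max`).
#' @param tip_err_len_factor Length bound (in multiples of k) for the
#'   error-tip rule.
#' @param tip_err_cov_ratio Error tips must have coverage below this fraction
#'   of the alternative edge's coverage.
#' @param tip_err_hamming_max Maximum Hamming distance between a tip and its
#'   alternative edge for the error-tip rule.
#' @param tip_at_frac Tips with A/T content strictly above this fraction are
#'   removed as low-complexity (poly-A artefacts).
#' @param bulge_len_diff_max Maximum relative length difference
#'   (`|l1 - l2| / max(l1, l2)`) for two parallel edges to be collapsed.
#' @param iso_edge_cov_max Isolated edges with coverage strictly below this
#'   and length at most the read length are dropped.
#' @param chimeric_loop_min_adj_len Minimum length (in multiples of k) of the
#'   single incident edge at a chimeric-loop vertex.
#' @param L_ov Minimum exact suffix-prefix overlap for overlap-based gap
#'   closing (bp).
#' @param N_ov Minimum number of spanning read pairs required together with
#'   an exact overlap.
#' @param N_min Number of spanning read pairs sufficient on their own to
#'   close a gap.
#' @param C Relative score band for multi-extension: every extension scoring
#'   above `max_score / C` is kept.
#' @param theta Absolute score threshold for read-pair extension (raw pair
#'   count).
#' @param delta Coverage fold-change required between competing extension
#'   and alternative edges in the coverage-based extender.
#' @param omega Coverage-persistence band: the on-path alternative and the
#'   chosen extension must have coverages within a factor `omega` of each
#'   other.
#' @param C_min Minimum coverage of an extension resolved by coverage alone.
#' @param k_low_min Floor for the lower k-mer size.
#' @param strand_split_ratio Dominance ratio concretising "much greater"
#'   for strand-based edge splitting.
#' @param strand_split_min_cov Minimum mean strand coverage on the dominant
#'   strand for a split.
#' @param max_edge_multiplicity Maximum number of times one edge (or its
#'   twin) may appear in a single path; guarantees termination on cycles.
#' @param max_paths_per_seed Cap on the number of forked paths grown from a
#'   single seed edge.
#' @return An object of class `assembly_params` (a named list).
#' @export
#' @examples
#' p <- assembly_params()
#' p$L_ov
assembly_params <- function(tip_short_len_factor = 2,
                            tip_short_cov_max = 1.0,
                            tip_err_len_factor = 4,
                            tip_err_cov_ratio = 0.5,
                            tip_err_hamming_max = 3,
                            tip_at_frac = 0.80,
                            bulge_len_diff_max = 0.10,
                            iso_edge_cov_max = 2.0,
                            chimeric_loop_min_adj_len = 2,
                            L_ov = 8L,
                            N_ov = 1L,
                            N_min = 5L,
                            C = 1.5,
                            theta = 1.0,
                            delta = 2.0,
                            omega = 10.0,
                            C_min = 2.0,
                            k_low_min = 29L,
                            strand_split_ratio = 10.0,
                            strand_split_min_cov = 1.0,
                            max_edge_multiplicity = 4L,
                            max_paths_per_seed = 64L) {
  p <- list(
    tip_short_len_factor = tip_short_len_factor,
    tip_short_cov_max = tip_short_cov_max,
    tip_err_len_factor = tip_err_len_factor,
    tip_err_cov_ratio = tip_err_cov_ratio,
    tip_err_hamming_max = tip_err_hamming_max,
    tip_at_frac = tip_at_frac,
    bulge_len_diff_max = bulge_len_diff_max,
    iso_edge_cov_max = iso_edge_cov_max,
    chimeric_loop_min_adj_len = chimeric_loop_min_adj_len,
    L_ov = as.integer(L_ov),
    N_ov = as.integer(N_ov),
    N_min = as.integer(N_min),
    C = C,
    theta = theta,
    delta = delta,
    omega = omega,
    C_min = C_min,
    k_low_min = as.integer(k_low_min),
    strand_split_ratio = strand_split_ratio,
    strand_split_min_cov = strand_split_min_cov,
    max_edge_multiplicity = as.integer(max_edge_multiplicity),
    max_paths_per_seed = as.integer(max_paths_per_seed)
  )
  stopifnot(
    all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))),
    p$C > 1,
    p$omega > p$delta
  )
  class(p) <- "assembly_params"
  p
}
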