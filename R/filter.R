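# Tiered output filtration. Non-mRNA contamination (intergenic fragments,
# unremoved artefacts) is mostly short, low-covered and isolated in the
# graph; three presets trade sensitivity against specificity. The preset
# values here are this package's own calibration, configurable per run.

#' Filtration presets
#'
#' Returns the threshold set for one of the three filtration levels:
#' `soft` (most sensitive), `normal` (default) and `hard` (most specific).
#' Thresholds are monotone across presets, so the output sets form a chain
#' hard within normal within soft.
#'
#' @param name One of `"soft"`, `"normal"`, `"hard"`.
#' @param read_length Read length in bp; isolated-contig length cutoffs
#'   scale with it.
#' @return A list of class `filtration_preset` with `name`, `min_len`,
#'   `min_cov`, `drop_isolated_below_len`.
#' @export
filtration_preset <- function(name = c("normal", "soft", "hard"),
                              read_length) {
  name <- match.arg(name)
  p <- switch(name,
    soft = list(min_len = 0L, min_cov = 0,
                drop_isolated_below_len = as.integer(read_length / 2)),
    normal = list(min_len = 0L, min_cov = 1.0,
                  drop_isolated_below_len = as.integer(read_length) + 1L),
    hard = list(min_len = 200L, min_cov = 2.0,
                drop_isolated_below_len = 2L * as.integer(read_length) + 1L)
  )
  structure(c(list(name = name), p), class = "filtration_preset")
}

#' Filter assembled transcripts
#'
#' Drops contigs below the preset's length or coverage thresholds;
#' isolated single-edge contigs are additionally dropped below the
#' preset's isolated-length cutoff. A pure function of contig length,
#' coverage and isolation flag.
#'
#' @param contigs Contig data.frame from [orient_paths()] (columns
#'   `length`, `cov`, `isolated`).
#' @param preset Preset name or a [filtration_preset()] object.
#' @param read_length Read length in bp (used when `preset` is a name).
#' @return The retained contig rows.
#' @export
filter_transcripts <- function(contigs, preset = "normal", read_length) {
  if (is.character(preset)) preset <- filtration_preset(preset, read_length)
  stopifnot(inherits(preset, "filtration_preset"))
  if (nrow(contigs) == 0) return(contigs)
  keep <- contigs$length >= preset$min_len &
    contigs$cov >= preset$min_cov &
    !(contigs$isolated & contigs$length < preset$drop_isolated_below_len)
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
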