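# Count/ratio reporters used for dataset and proteome summaries.

#' Total of per-type site counts
#'
#' @param counts Non-negative integer counts.
#' @return Their sum as an integer-valued numeric.
#' @export
count_total <- function(counts) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  sum(counts)
}

#' Modification percentage of an amino acid
#'
#' Share of a residue's proteome-wide occurrences that are (predicted or
#' verified) phosphosites, as a percentage.
#'
#' @param n_sites Number of phosphosites.
#' @param n_residues Total number of occurrences of the residue.
#' @param digits Rounding digits for the printed percentage.
#' @return Percentage, rounded.
#' @export
modification_ratio <- function(n_sites, n_residues, digits = 2L) {
  stopifnot(n_residues > 0, n_sites >= 0)
  round(100 * n_sites / n_residues, digits)
}

#' Mean number of sites per protein
#'
#' @param n_sites Number of sites.
#' @param n_proteins Number of proteins carrying them.
#' @param digits Rounding digits.
#' @return Sites per protein, rounded.
#' @export
per_protein_mean <- function(n_sites, n_proteins, digits = 2L) {
  stopifnot(n_proteins > 0, n_sites >= 0)
  round(n_sites / n_proteins, digits)
}

#' Negative:positive class balance of a benchmark
#'
#' @param n_negative,n_positive Class sizes.
#' @param digits Rounding digits.
#' @return The negative:positive ratio, rounded (e.g. 3.43 for a 1:3.43
#'   dataset).
#' @export
class_balance <- function(n_negative, n_positive, digits = 2L) {
  stopifnot(n_positive > 0, n_negative >= 0)
  round(n_negative / n_positive, digits)
}

#' Summary table of a per-type benchmark
#'
#' @param benchmark Named list of example data frames (one per site type)
#'   with a `label` column.
#' @return Data frame with positives, negatives and the class balance per
#'   type.
#' @export
benchmark_summary <- function(benchmark) {
  rows <- lapply(names(benchmark), function(ty) {
    ex <- benchmark[[ty]]
    n_pos <- sum(ex$label == 1L)
    n_neg <- sum(ex$label == 0L)
    data.frame(site_type = ty, n_positive = n_pos, n_negative = n_neg,
               ratio = class_balance(n_neg, n_pos), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
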