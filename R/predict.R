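# End-user prediction: scan proteins with trained bundles and grade calls.

MIN_QUERY_LENGTH <- 17L  # query sequences must be longer than 16 residues

#' Reliability grade of a prediction probability
#'
#' `high` for 0.85 < p <= 1.00, `middle` for 0.70 < p <= 0.85, `low` for
#' 0.50 < p <= 0.70; probabilities at or below 0.50 are not emitted by the
#' predictor and grade as `NA`.
#'
#' @param p Numeric probabilities in `[0, 1]`.
#' @return Character vector of grades.
#' @export
grade_probability <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- rep(NA_character_, length(p))
  out[p > 0.50 & p <= 0.70] <- "low"
  out[p > 0.70 & p <= 0.85] <- "middle"
  out[p > 0.85] <- "high"
  out
}

#' Predict N-phosphosites on protein sequences
#'
#' Every H/K/R residue of each protein is windowed, encoded with the
#' corresponding bundle's feature combination and scored; sites whose
#' probability exceeds the report threshold are emitted with a reliability
#' grade, sorted by type then protein then ascending position.
#'
#' @param proteins Protein data frame (`id`, `sequence`); every sequence
#'   must be longer than 16 residues.
#' @param bundles Named list of `model_bundle`s keyed by site type.
#' @param types Site types to scan; defaults to the bundles available.
#' @param report_threshold Minimum probability for a site to be reported.
#' @param w Window width.
#' @return Data frame with `protein_id`, `position`, `residue`, `site_type`,
#'   `probability`, `grade`.
#' @export
predict_sites <- function(proteins, bundles, types = names(bundles),
                          report_threshold = 0.50, w = 31L) {
  validate_proteins(proteins)
  short <- nchar(proteins$sequence) < MIN_QUERY_LENGTH
  if (any(short)) {
    stop("query sequences must be longer than 16 residues; rejected: ",
         paste(proteins$id[short], collapse = ", "))
  }
  stopifnot(all(types %in% names(SITE_RESIDUES)))
  missing <- setdiff(types, names(bundles))
  if (length(missing)) {
    stop("no model bundle for type(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(types, function(ty) {
    letter <- SITE_RESIDUES[[ty]]
    hits <- lapply(seq_len(nrow(proteins)), function(i) {
      pos <- which(strsplit(proteins$sequence[i], "",
                            fixed = TRUE)[[1L]] == letter)
      if (length(pos) == 0L) return(NULL)
      data.frame(protein_id = proteins$id[i], position = pos,
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, hits)
    if (is.null(cand)) return(NULL)
    win <- extract_windows(proteins, cand, w = w)
    prob <- predict(bundles[[ty]], win$peptide)
    keep <- prob > report_threshold
    if (!any(keep)) return(NULL)
    data.frame(protein_id = win$protein_id[keep],
               position = win$position[keep],
               residue = win$residue[keep],
               site_type = ty,
               probability = prob[keep],
               grade = grade_probability(prob[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), site_type = character(),
                      probability = numeric(), grade = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(match(out$site_type, names(SITE_RESIDUES)),
                   out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proteome-wide scan with a high-confidence threshold
#'
#' Predicts sites at the given probability threshold (0.85 by default for
#' high-reliability calls) and reports distinct site and protein counts per
#' type. Experimentally annotated positions are excluded when an annotation
#' table is supplied.
#'
#' @param proteins Protein data frame.
#' @param bundles Named list of `model_bundle`s.
#' @param threshold Probability threshold.
#' @param annotations Optional annotation data frame (`protein_id`,
#'   `position`) of known sites to exclude.
#' @param types Site types to scan.
#' @return List with `counts` (data frame of per-type site/protein counts
#'   plus a total row) and `sites` (the predicted-site data frame).
#' @export
proteome_scan <- function(proteins, bundles, threshold = 0.85,
                          annotations = NULL, types = names(bundles)) {
  sites <- if (nrow(proteins) == 0L) {
    data.frame(protein_id = character(), position = integer(),
               residue = character(), site_type = character(),
               probability = numeric(), grade = character())
  } else {
    predict_sites(proteins, bundles, types = types,
                  report_threshold = threshold)
  }
  if (!is.null(annotations) && nrow(sites) > 0L) {
    known <- paste(annotations$protein_id, annotations$position)
    sites <- sites[!(paste(sites$protein_id, sites$position) %in% known), ,
                   drop = FALSE]
  }
  per_type <- lapply(types, function(ty) {
    s <- sites[sites$site_type == ty, , drop = FALSE]
    data.frame(site_type = ty, n_sites = nrow(s),
               n_proteins = length(unique(s$protein_id)),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, per_type)
  counts <- rbind(counts,
                  data.frame(site_type = "total",
                             n_sites = count_total(counts$n_sites),
                             n_proteins = length(unique(sites$protein_id))))
  list(counts = counts, sites = sites)
}

#' Write predicted sites as TSV plus a plain-text mirror
#'
#' Probabilities are printed to 4 decimals; grades are assigned on the
#' full-precision values.
#'
#' @param sites Predicted-site data frame from [predict_sites()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.txt`.
#' @return The two paths, invisibly.
#' @export
write_predictions <- function(sites, prefix) {
  out <- sites
  out$probability <- sprintf("%.4f", out$probability)
  tsv <- paste0(prefix, ".tsv")
  write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- paste0(prefix, ".txt")
  writeLines(c(
    sprintf("%-12s %8s %7s %6s %11s %6s",
            "protein_id", "position", "residue", "type", "probability",
            "grade"),
    sprintf("%-12s %8d %7s %6s %11s %6s", out$protein_id, out$position,
            out$residue, out$site_type, out$probability, out$grade)
  ), txt)
  invisible(c(tsv = tsv, txt = txt))
}
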