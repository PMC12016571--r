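# Benchmark construction: positives from experimentally annotated sites,
# negatives via the four-step rule (same proteins, RSA ceiling per residue,
# window extraction, identity filter against the positives).

#' Configuration of the negative-set rule
#'
#' Per-residue relative solvent accessibility ceilings (negative candidates
#' above the ceiling are considered exposed and excluded) and the ungapped
#' sequence-identity threshold against the positive set.
#'
#' @param rsa_threshold Named numeric, RSA ceilings for H, K and R.
#' @param identity_threshold Fraction in (0, 1]; candidates with identity at
#'   or above it to any positive window are removed.
#' @return A `negative_config` list.
#' @export
negative_config <- function(rsa_threshold = c(H = 0.12, K = 0.30, R = 0.20),
                            identity_threshold = 0.30) {
  stopifnot(all(c("H", "K", "R") %in% names(rsa_threshold)),
            all(rsa_threshold >= 0 & rsa_threshold <= 1),
            identity_threshold > 0, identity_threshold <= 1)
  structure(list(rsa_threshold = rsa_threshold,
                 identity_threshold = identity_threshold),
            class = "negative_config")
}

#' Build the positive benchmark examples
#'
#' One labeled example per distinct peptide window per phosphorylation type;
#' sites in different proteins sharing an identical window collapse to one
#' example (redundant peptides are excluded).
#'
#' @param sites Annotation data frame (`protein_id`, `position`, `residue`,
#'   with residue in H/K/R).
#' @param proteins Protein data frame (`id`, `sequence`).
#' @param w Odd window width.
#' @return Data frame of examples (`peptide`, `protein_id`, `position`,
#'   `residue`, `site_type`, `label = 1`), with a `summary` attribute giving
#'   distinct window and protein counts per type.
#' @export
build_positives <- function(sites, proteins, w = 31L) {
  stopifnot(all(sites$residue %in% SITE_RESIDUES))
  validate_sites(sites, proteins)
  win <- extract_windows(proteins, sites, w = w)
  win$site_type <- site_type_of(win$residue)
  keep <- !duplicated(win[, c("site_type", "peptide")])
  out <- win[keep, c("peptide", "protein_id", "position", "residue",
                     "site_type")]
  out$label <- 1L
  rownames(out) <- NULL
  counts <- lapply(split(out, out$site_type), function(d) {
    c(n_windows = nrow(d), n_proteins = length(unique(d$protein_id)))
  })
  attr(out, "summary") <- counts
  out
}

# Ungapped identity between equal-length windows: matching non-pad positions
# divided by window length. Returns, per row of `x`, the maximum number of
# matching positions against any window in `y`, computed via a sparse
# one-hot cross-product (pads and ambiguity letters carry no one-hot bit, so
# they never match).
max_match_counts <- function(x, y, chunk = 4000L) {
  mx <- encoder_letters(peptide_matrix(x))
  my <- encoder_letters(peptide_matrix(y))
  stopifnot(ncol(mx) == ncol(my))
  w <- ncol(mx)
  lev <- AA20
  one_hot <- function(m) {
    n <- nrow(m)
    code <- match(as.vector(m), lev)           # NA for pads
    pos <- rep(seq_len(w), each = n)
    keep <- !is.na(code)
    Matrix::sparseMatrix(
      i = rep(seq_len(n), w)[keep],
      j = ((pos - 1L) * length(lev) + code)[keep],
      x = 1,
      dims = c(n, w * length(lev))
    )
  }
  hy <- one_hot(my)
  out <- integer(nrow(mx))
  for (start in seq(1L, nrow(mx), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(mx))
    hx <- one_hot(mx[idx, , drop = FALSE])
    cross <- as.matrix(hx %*% Matrix::t(hy))
    out[idx] <- as.integer(apply(cross, 1L, max))
  }
  out
}

#' Remove candidate windows homologous to the positive set
#'
#' A candidate is removed iff its ungapped end-to-end identity (matching
#' non-pad positions / window length) to some positive window is greater
#' than or equal to the threshold.
#'
#' @param candidates Character vector of candidate peptide windows.
#' @param positives Character vector of positive peptide windows (same
#'   length as the candidates' windows).
#' @param identity_threshold Identity fraction at/above which a candidate is
#'   removed.
#' @return Logical vector, `TRUE` where the candidate is kept.
#' @export
homology_filter <- function(candidates, positives, identity_threshold = 0.30) {
  if (length(positives) == 0L) return(rep(TRUE, length(candidates)))
  if (length(candidates) == 0L) return(logical(0L))
  w <- unique(nchar(c(candidates, positives)))
  if (length(w) != 1L) stop("candidate and positive windows differ in length")
  best <- max_match_counts(candidates, positives)
  best / w < identity_threshold - 1e-12
}

#' Build the negative benchmark examples
#'
#' Implements the four-step negative rule: (1) candidate H/K/R residues are
#' drawn only from proteins carrying at least one annotated phosphosite,
#' excluding annotated positions; (2) residues whose RSA exceeds the
#' per-residue ceiling (exposed residues) are excluded, and candidates with
#' no RSA value are dropped (counted, not fatal); (3) 31-residue windows are
#' extracted; (4) windows with identity at/above the threshold to any
#' positive window of the same type are removed. Duplicate windows collapse.
#'
#' @param proteins Protein data frame.
#' @param sites Annotated phosphosite data frame (defines the protein pool
#'   and the excluded positions).
#' @param rsa Per-residue RSA values: either a named list of numeric vectors
#'   (one per protein, indexed by position) or a data frame with
#'   `protein_id`, `position`, `rsa`.
#' @param cfg A [negative_config()].
#' @param positives Positive examples from [build_positives()]; built from
#'   `sites` when omitted.
#' @param types Site types to build negatives for.
#' @param w Odd window width.
#' @return Data frame of examples (`label = 0`) with columns as in
#'   [build_positives()] plus `rsa`; attribute `n_missing_rsa` counts
#'   candidates dropped for lack of an RSA value.
#' @export
build_negatives <- function(proteins, sites, rsa, cfg = negative_config(),
                            positives = NULL,
                            types = c("pHis", "pLys", "pArg"), w = 31L) {
  stopifnot(all(types %in% names(SITE_RESIDUES)))
  if (is.null(positives)) positives <- build_positives(sites, proteins, w = w)
  pool <- proteins[proteins$id %in% unique(sites$protein_id), , drop = FALSE]
  letters_wanted <- unname(SITE_RESIDUES[types])

  # all candidate residues of the requested types in the pool
  cand <- do.call(rbind, lapply(seq_len(nrow(pool)), function(i) {
    chars <- strsplit(pool$sequence[i], "", fixed = TRUE)[[1L]]
    pos <- which(chars %in% letters_wanted)
    if (length(pos) == 0L) return(NULL)
    data.frame(protein_id = pool$id[i], position = pos,
               residue = chars[pos], stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no candidate H/K/R residues in the annotated proteins")
  }

  # exclude annotated phosphosite positions
  site_key <- paste(sites$protein_id, sites$position)
  cand <- cand[!(paste(cand$protein_id, cand$position) %in% site_key), ,
               drop = FALSE]

  # RSA lookup and exposure filter
  cand$rsa <- lookup_rsa(rsa, cand$protein_id, cand$position)
  n_missing <- sum(is.na(cand$rsa))
  cand <- cand[!is.na(cand$rsa), , drop = FALSE]
  keep <- cand$rsa <= cfg$rsa_threshold[cand$residue]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no negative candidates survive the RSA filter")

  win <- extract_windows(proteins, cand, w = w)
  win$rsa <- cand$rsa
  win$site_type <- site_type_of(win$residue)

  # identity filter against the positives of the same type, then dedupe
  kept <- unlist(lapply(split(seq_len(nrow(win)), win$site_type),
                        function(ix) {
    pos_pep <- positives$peptide[positives$site_type == win$site_type[ix[1L]]]
    ix[homology_filter(win$peptide[ix], pos_pep, cfg$identity_threshold)]
  }), use.names = FALSE)
  win <- win[sort(kept), , drop = FALSE]
  win <- win[!duplicated(win[, c("site_type", "peptide")]), , drop = FALSE]

  out <- win[, c("peptide", "protein_id", "position", "residue", "site_type",
                 "rsa")]
  out$label <- 0L
  rownames(out) <- NULL
  attr(out, "n_missing_rsa") <- n_missing
  out
}

lookup_rsa <- function(rsa, protein_id, position) {
  if (is.data.frame(rsa)) {
    key <- paste(rsa$protein_id, rsa$position)
    return(rsa$rsa[match(paste(protein_id, position), key)])
  }
  stopifnot(is.list(rsa), !is.null(names(rsa)))
  vapply(seq_along(protein_id), function(i) {
    v <- rsa[[protein_id[i]]]
    if (is.null(v) || position[i] > length(v)) return(NA_real_)
    v[position[i]]
  }, numeric(1L))
}

#' Combine positive and negative examples of one site type
#'
#' @param positives,negatives Example data frames from [build_positives()]
#'   and [build_negatives()].
#' @param site_type One of `"pHis"`, `"pLys"`, `"pArg"`.
#' @return Data frame with `peptide`, `label`, `site_type` (plus provenance
#'   columns), positives first.
#' @export
benchmark_examples <- function(positives, negatives, site_type) {
  stopifnot(site_type %in% names(SITE_RESIDUES))
  cols <- c("peptide", "protein_id", "position", "residue", "site_type",
            "label")
  pos <- positives[positives$site_type == site_type, cols]
  neg <- negatives[negatives$site_type == site_type, cols]
  neg$rsa <- negatives$rsa[negatives$site_type == site_type]
  pos$rsa <- NA_real_
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Plan of repeated train/test splits with internal cross-validation folds
#'
#' @param train_fraction Fraction of examples used for training.
#' @param n_repeats Number of independent shuffled splits.
#' @param k_folds Folds for internal cross-validation.
#' @param cv_repeats Repeats of the k-fold cross-validation.
#' @param seed Top-level seed; all per-repeat seeds derive from it.
#' @return A `split_plan` list.
#' @export
split_plan <- function(train_fraction = 0.8, n_repeats = 5L, k_folds = 10L,
                       cv_repeats = 10L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, k_folds >= 2L,
            n_repeats >= 1L, cv_repeats >= 1L)
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 k_folds = as.integer(k_folds),
                 cv_repeats = as.integer(cv_repeats),
                 seed = as.integer(seed)),
            class = "split_plan")
}

# Stratified assignment of indices to k folds, one class at a time.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < k) stop("class ", cl, " has fewer examples (",
                              length(idx), ") than folds (", k, ")")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified train/test splits
#'
#' Each repeat is an independent seeded stratified shuffle preserving the
#' class ratio within one example per part; each training set additionally
#' carries a stratified k-fold partition.
#'
#' @param labels Integer labels (0/1) of the examples.
#' @param plan A [split_plan()].
#' @return List of length `n_repeats`; each element has `train`, `test`
#'   (disjoint index vectors covering all examples) and `folds` (list of
#'   `k_folds` index vectors partitioning `train`).
#' @export
split_dataset <- function(labels, plan = split_plan()) {
  if (length(unique(labels)) < 2L) {
    stop("stratification needs both classes present")
  }
  if (min(table(labels)) < 2L) stop("need at least 2 examples per class")
  lapply(seq_len(plan$n_repeats), function(r) {
    set.seed(plan$seed * 1000L + r)
    train <- integer(0L)
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      n_train <- round(plan$train_fraction * length(idx))
      train <- c(train, idx[seq_len(n_train)])
    }
    train <- sort(train)
    test <- setdiff(seq_along(labels), train)
    fold_id <- stratified_folds(labels[train], plan$k_folds)
    folds <- split(train, fold_id)
    names(folds) <- NULL
    list(train = train, test = test, folds = folds)
  })
}

#' Write a benchmark as peptide FASTA plus TSV label table
#'
#' @param examples Example data frame (one site type).
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_benchmark <- function(examples, prefix) {
  ids <- sprintf("%s_%d_%s", examples$protein_id, examples$position,
                 ifelse(examples$label == 1L, "pos", "neg"))
  fasta <- paste0(prefix, ".fasta")
  writeLines(paste0(">", ids, "\n", examples$peptide), fasta)
  tsv <- paste0(prefix, ".tsv")
  write.table(examples, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Write split indices as JSON
#'
#' @param splits Result of [split_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(splits, path, auto_unbox = FALSE)
  invisible(path)
}
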