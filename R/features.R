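# Feature encodings for phosphosite-centered peptide windows:
#   AAC       -- 20-dim amino-acid composition
#   HQI8      -- 8 high-quality AAindex physicochemical indices per residue
#   BLOSUM62  -- the residue's 20-long BLOSUM62 substitution row per position
# Position-major layout for HQI8/BLOSUM62: one block per window position.

.feature_env <- new.env(parent = emptyenv())

# AAindex accessions of the HQI8 high-quality index set (fuzzy-clustering
# representatives of the AAindex property space).
HQI8_ACCESSIONS <- c("BLAM930101", "BIOV880101", "MAXF760101", "TSAJ990101",
                     "NAKH920108", "CEDJ970104", "LIFS790101", "MIYS990104")

FEATURE_SETS <- c("AAC", "HQI8", "BLOSUM62")

#' The HQI8 physicochemical property table
#'
#' Eight AAindex properties per canonical amino acid. By default the values
#' are taken from the AAindex database shipped with \pkg{seqinr}, keyed by the
#' HQI8 accessions. A custom table may be supplied as a TSV with an `aa`
#' column (one-letter code) followed by one column per property.
#'
#' @param path Optional path to a replacement TSV table.
#' @return A 20 x 8 numeric matrix, rows named by amino acid, columns by
#'   AAindex accession.
#' @export
hqi8_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.feature_env$hqi8)) return(.feature_env$hqi8)
    aaindex <- NULL
    utils::data("aaindex", package = "seqinr", envir = environment())
    three <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
               "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
               "Tyr", "Val")
    one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
             "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    tab <- vapply(HQI8_ACCESSIONS, function(acc) {
      entry <- aaindex[[acc]]
      if (is.null(entry)) stop("AAindex accession not found: ", acc)
      v <- entry$I
      stopifnot(identical(names(v), three))
      v
    }, numeric(20L))
    rownames(tab) <- one
    tab <- tab[AA20, , drop = FALSE]
    if (anyNA(tab)) stop("missing values in HQI8 table")
    .feature_env$hqi8 <- tab
    return(tab)
  }
  raw <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("aa" %in% names(raw), ncol(raw) == 9L)
  tab <- as.matrix(raw[, setdiff(names(raw), "aa"), drop = FALSE])
  rownames(tab) <- raw$aa
  if (!setequal(rownames(tab), AA20) || anyNA(tab)) {
    stop("HQI8 table must cover exactly the 20 canonical amino acids")
  }
  tab[AA20, , drop = FALSE]
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-delimited matrix format (comment lines
#' starting with `#`, a header row of column letters, one labeled row per
#' residue).
#'
#' @param path Path to the matrix file.
#' @return A square integer matrix with residue row/column names.
#' @export
read_blosum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  lab <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  vals
}

#' The BLOSUM62 encoding matrix (21 rows x 20 columns)
#'
#' Rows are the 20 canonical amino acids plus the pad character `"-"`,
#' columns the 20 canonical amino acids. The pad row represents "any one of
#' the 20 amino acids" and defaults to the matrix's X/any row. The default
#' values come from \pkg{Biostrings}' published BLOSUM62 data; a replacement
#' matrix (e.g. from [read_blosum()]) may be supplied.
#'
#' @param matrix Optional full substitution matrix with at least the 20
#'   canonical rows/columns; an `X` row is used for the pad character when
#'   present.
#' @return A 21 x 20 numeric matrix.
#' @export
blosum62_matrix <- function(matrix = NULL) {
  if (is.null(matrix)) {
    if (!is.null(.feature_env$blosum62)) return(.feature_env$blosum62)
    BLOSUM62 <- NULL
    utils::data("BLOSUM62", package = "Biostrings", envir = environment())
    matrix <- BLOSUM62
    memo <- TRUE
  } else {
    memo <- FALSE
  }
  if (!all(AA20 %in% rownames(matrix)) || !all(AA20 %in% colnames(matrix))) {
    stop("substitution matrix must contain the 20 canonical amino acids")
  }
  pad_row <- if ("X" %in% rownames(matrix)) {
    matrix["X", AA20]
  } else if (PAD_CHAR %in% rownames(matrix)) {
    matrix[PAD_CHAR, AA20]
  } else {
    stop("substitution matrix has neither an 'X' nor a '-' row for padding")
  }
  out <- rbind(matrix[AA20, AA20, drop = FALSE], `-` = pad_row)
  if (memo) .feature_env$blosum62 <- out
  out
}

# Map window letters to encoder row labels: canonical kept, pad and
# ambiguity letters collapse to the pad character.
encoder_letters <- function(mat) {
  mat[mat %in% c(PAD_CHAR, AA_AMBIGUOUS)] <- PAD_CHAR
  bad <- !(mat %in% c(AA20, PAD_CHAR))
  if (any(bad)) {
    stop("letter(s) with no encoding row: ",
         paste(unique(mat[bad]), collapse = ", "))
  }
  mat
}

#' Amino-acid composition (AAC) encoding
#'
#' Frequency of each of the 20 canonical amino acids among the canonical
#' residues of the window; pad and ambiguity characters are excluded from
#' both numerator and denominator, so components sum to 1.
#'
#' @param peptides Character vector of equal-length peptide windows.
#' @return Numeric matrix, one row per window, 20 named columns.
#' @export
encode_aac <- function(peptides) {
  mat <- encoder_letters(peptide_matrix(peptides))
  counts <- vapply(AA20, function(a) rowSums(mat == a),
                   numeric(length(peptides)))
  if (length(peptides) == 1L) counts <- matrix(counts, nrow = 1L,
                                               dimnames = list(NULL, AA20))
  denom <- rowSums(counts)
  if (any(denom == 0)) {
    stop("window(s) with no canonical residue cannot be AAC-encoded")
  }
  out <- counts / denom
  colnames(out) <- paste0("AAC_", AA20)
  out
}

#' HQI8 physicochemical encoding
#'
#' Position-major concatenation of the 8 HQI8 property values of each window
#' residue (`w * 8` columns; 248 for the default 31-mer). Pad/ambiguous
#' positions contribute an 8-long zero block.
#'
#' @param peptides Character vector of equal-length peptide windows.
#' @param table HQI8 table from [hqi8_table()].
#' @return Numeric matrix, one row per window.
#' @export
encode_hqi8 <- function(peptides, table = hqi8_table()) {
  mat <- encoder_letters(peptide_matrix(peptides))
  w <- ncol(mat)
  n <- nrow(mat)
  out <- matrix(0, nrow = n, ncol = w * 8L)
  for (pos in seq_len(w)) {
    idx <- match(mat[, pos], rownames(table))
    block <- table[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    block[is.na(idx), ] <- 0
    out[, (pos - 1L) * 8L + seq_len(8L)] <- block
  }
  colnames(out) <- as.vector(outer(colnames(table),
                                   sprintf("HQI8_p%02d", seq_len(w)),
                                   function(a, p) paste0(p, "_", a)))
  out
}

#' BLOSUM62 row encoding
#'
#' Position-major concatenation of the 20-long BLOSUM62 row of each window
#' letter (`w * 20` columns; 620 for the default 31-mer). Pad and ambiguity
#' letters use the matrix's pad ("any amino acid") row.
#'
#' @param peptides Character vector of equal-length peptide windows.
#' @param matrix Encoding matrix from [blosum62_matrix()].
#' @return Numeric matrix, one row per window.
#' @export
encode_blosum62 <- function(peptides, matrix = blosum62_matrix()) {
  mat <- encoder_letters(peptide_matrix(peptides))
  w <- ncol(mat)
  n <- nrow(mat)
  out <- matrix(0, nrow = n, ncol = w * 20L)
  for (pos in seq_len(w)) {
    idx <- match(mat[, pos], rownames(matrix))
    out[, (pos - 1L) * 20L + seq_len(20L)] <- matrix[idx, , drop = FALSE]
  }
  colnames(out) <- as.vector(outer(AA20,
                                   sprintf("B62_p%02d", seq_len(w)),
                                   function(a, p) paste0(p, "_", a)))
  out
}

#' Encode windows with a combination of feature sets
#'
#' Concatenates the selected encodings in the fixed order AAC, HQI8,
#' BLOSUM62. The seven admissible combinations of a 31-mer yield feature
#' vectors of length 20, 248, 620, 268, 640, 868 and 888.
#'
#' @param peptides Character vector of equal-length peptide windows.
#' @param combo Non-empty subset of `c("AAC", "HQI8", "BLOSUM62")`.
#' @param hqi8 HQI8 table.
#' @param blosum BLOSUM62 encoding matrix.
#' @return Numeric feature matrix with named columns; attribute `combo`
#'   records the combination.
#' @export
encode_windows <- function(peptides, combo = FEATURE_SETS,
                           hqi8 = hqi8_table(), blosum = blosum62_matrix()) {
  combo <- match.arg(combo, FEATURE_SETS, several.ok = TRUE)
  if (length(combo) == 0L) stop("combo must name at least one feature set")
  combo <- FEATURE_SETS[FEATURE_SETS %in% combo]
  parts <- lapply(combo, function(f) {
    switch(f,
           AAC = encode_aac(peptides),
           HQI8 = encode_hqi8(peptides, hqi8),
           BLOSUM62 = encode_blosum62(peptides, blosum))
  })
  out <- do.call(cbind, parts)
  attr(out, "combo") <- combo
  out
}

#' Feature-vector length of a combination
#'
#' @param combo Subset of `c("AAC", "HQI8", "BLOSUM62")`.
#' @param w Window width.
#' @return Integer number of features.
#' @export
combo_length <- function(combo, w = 31L) {
  combo <- match.arg(combo, FEATURE_SETS, several.ok = TRUE)
  sum(c(AAC = 20L, HQI8 = 8L * w, BLOSUM62 = 20L * w)[combo])
}
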