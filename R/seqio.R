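#' @importFrom stats rbeta rbinom rnorm runif setNames pbinom chisq.test sd
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Canonical amino-acid alphabet, fixed ordering used by every encoder.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity letters accepted on input; encoders treat them as pad-equivalent.
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")

PAD_CHAR <- "-"

SITE_RESIDUES <- c(pHis = "H", pLys = "K", pArg = "R")

#' Map a residue letter (H/K/R) to its N-phosphorylation type label
#'
#' @param residue Character vector of residue letters.
#' @return Character vector with entries `"pHis"`, `"pLys"` or `"pArg"`.
#' @export
site_type_of <- function(residue) {
  out <- names(SITE_RESIDUES)[match(residue, SITE_RESIDUES)]
  if (anyNA(out)) {
    stop("residue letters must be one of H, K, R; got: ",
         paste(unique(residue[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 canonical amino-acid
#' letters plus the ambiguity letters B, Z, X, U, O. Multi-line records are
#' concatenated. An empty file yields a zero-row set.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param alphabet `"protein"` (default) or `"peptide"`; the peptide
#'   alphabet additionally admits the `"-"` pad character, for files of
#'   extracted windows.
#' @return A data frame with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path, alphabet = c("protein", "peptide")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    if (all(!nzchar(trimws(raw)))) {
      return(data.frame(id = character(), sequence = character(),
                        stringsAsFactors = FALSE))
    }
    stop("not a FASTA file (no '>' header found): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  prot <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  validate_proteins(prot, allow_pad = alphabet == "peptide")
  prot
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  validate_proteins(proteins)
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

validate_proteins <- function(proteins, allow_pad = FALSE) {
  stopifnot(is.data.frame(proteins),
            all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L) return(invisible(proteins))
  if (any(!nzchar(proteins$id))) stop("empty protein id")
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein ids: ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  }
  if (any(!nzchar(proteins$sequence))) {
    stop("empty sequence for record(s): ",
         paste(proteins$id[!nzchar(proteins$sequence)], collapse = ", "))
  }
  letters_ok <- c(AA20, AA_AMBIGUOUS, if (allow_pad) PAD_CHAR)
  ok <- grepl(paste0("^[", paste(letters_ok, collapse = ""), "]+$"),
              proteins$sequence)
  if (!all(ok)) {
    stop("illegal character in sequence of record(s): ",
         paste(proteins$id[!ok], collapse = ", "))
  }
  invisible(proteins)
}

#' Read a phosphosite annotation table
#'
#' Expects a TSV with header columns `protein_id`, `position`, `residue` and
#' optionally `rsa`, `structure_class`, `disorder`, `exposure`. Missing
#' optional values may be encoded as empty strings.
#'
#' @param path Path to the TSV file.
#' @return Data frame of site annotations.
#' @export
read_sites <- function(path) {
  stopifnot(file.exists(path))
  sites <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(sites))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  sites$position <- as.integer(sites$position)
  sites
}

#' Write a phosphosite annotation table
#'
#' @param sites Data frame of site annotations.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Validate site annotations against their protein sequences
#'
#' Checks that every annotation resolves to a position inside its protein and
#' that the annotated residue letter equals the sequence letter there.
#'
#' @param sites Data frame with `protein_id`, `position`, `residue`.
#' @param proteins Data frame with `id`, `sequence`.
#' @return `sites`, invisibly; stops with an informative error otherwise.
#' @export
validate_sites <- function(sites, proteins) {
  idx <- match(sites$protein_id, proteins$id)
  if (anyNA(idx)) {
    stop("site(s) reference unknown protein(s): ",
         paste(unique(sites$protein_id[is.na(idx)]), collapse = ", "))
  }
  len <- nchar(proteins$sequence)[idx]
  bad <- sites$position < 1L | sites$position > len
  if (any(bad)) {
    stop("site position out of range for: ",
         paste(sprintf("%s:%d", sites$protein_id[bad], sites$position[bad]),
               collapse = ", "))
  }
  actual <- substr(proteins$sequence[idx], sites$position, sites$position)
  bad <- actual != sites$residue
  if (any(bad)) {
    stop("annotated residue does not match sequence at: ",
         paste(sprintf("%s:%d (annotated %s, sequence %s)",
                       sites$protein_id[bad], sites$position[bad],
                       sites$residue[bad], actual[bad]),
               collapse = ", "))
  }
  invisible(sites)
}

#' Extract a phosphosite-centered peptide window
#'
#' Returns the `w`-mer centered at `position`; flanks that fall outside the
#' protein are padded with `"-"`. Coordinates are 1-based.
#'
#' @param sequence A single protein sequence string.
#' @param position 1-based center position.
#' @param w Odd window width (default 31).
#' @return The peptide window string of length `w`.
#' @export
extract_window <- function(sequence, position, w = 31L) {
  stopifnot(length(sequence) == 1L, length(position) == 1L)
  if (w %% 2L == 0L) stop("window width w must be odd, got ", w)
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("position ", position, " out of range [1, ", n, "]")
  }
  half <- (w - 1L) %/% 2L
  padded <- paste0(strrep(PAD_CHAR, half), sequence, strrep(PAD_CHAR, half))
  substr(padded, position, position + w - 1L)
}

#' Extract windows for a table of sites
#'
#' Vectorized companion of [extract_window()]. Windows containing ambiguity
#' letters (B, Z, X, U, O) are flagged; downstream encoders treat those
#' letters as pad-equivalent.
#'
#' @param proteins Data frame with `id`, `sequence`.
#' @param sites Data frame with `protein_id`, `position` (and optionally
#'   `residue`, which is validated when present).
#' @param w Odd window width.
#' @return Data frame with `protein_id`, `position`, `residue`, `peptide`,
#'   `n_pad`, `has_ambiguous`.
#' @export
extract_windows <- function(proteins, sites, w = 31L) {
  if (w %% 2L == 0L) stop("window width w must be odd, got ", w)
  if ("residue" %in% names(sites)) validate_sites(sites, proteins)
  idx <- match(sites$protein_id, proteins$id)
  if (anyNA(idx)) {
    stop("unknown protein(s): ",
         paste(unique(sites$protein_id[is.na(idx)]), collapse = ", "))
  }
  half <- (w - 1L) %/% 2L
  seqs <- proteins$sequence[idx]
  n <- nchar(seqs)
  bad <- sites$position < 1L | sites$position > n
  if (any(bad)) {
    stop("position out of range for: ",
         paste(sprintf("%s:%d", sites$protein_id[bad], sites$position[bad]),
               collapse = ", "))
  }
  padded <- paste0(strrep(PAD_CHAR, half), seqs, strrep(PAD_CHAR, half))
  pep <- substr(padded, sites$position, sites$position + w - 1L)
  res <- substr(seqs, sites$position, sites$position)
  n_pad <- pmax(0L, half + 1L - sites$position) +
    pmax(0L, sites$position + half - n)
  data.frame(
    protein_id = sites$protein_id,
    position = sites$position,
    residue = res,
    peptide = pep,
    n_pad = n_pad,
    has_ambiguous = grepl(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"),
                          pep),
    stringsAsFactors = FALSE
  )
}

# Split peptides into an n x w character matrix.
peptide_matrix <- function(peptides) {
  w <- unique(nchar(peptides))
  if (length(w) != 1L) stop("peptides must all have the same length")
  matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
         nrow = length(peptides), ncol = w, byrow = TRUE)
}
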