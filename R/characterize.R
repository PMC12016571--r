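# Enrichment and motif statistics: E-ratio with chi-squared comparison,
# structural propensity tables, and greedy motif-x-style motif discovery.

#' Enrichment ratio of a category among phosphosites
#'
#' `E-ratio = (m * N) / (M * n)` where `m` of `M` phosphosites and `n` of
#' `N` non-phosphosites fall in the category. Significance is assessed by
#' the chi-squared test on the 2x2 table `[[m, M-m], [n, N-n]]` (without
#' continuity correction by default).
#'
#' @param m,M Category and total phosphosite counts.
#' @param n,N Category and total non-phosphosite counts.
#' @param correct Apply Yates continuity correction.
#' @return List with `ratio`, `p` and the chi-squared `statistic`.
#' @export
e_ratio <- function(m, M, n, N, correct = FALSE) {
  stopifnot(m >= 0, n >= 0, m <= M, n <= N, N > 0)
  if (n == 0 || M == 0) stop("E-ratio undefined: n and M must be positive")
  tbl <- matrix(c(m, M - m, n, N - n), nrow = 2L, byrow = TRUE)
  test <- suppressWarnings(chisq.test(tbl, correct = correct))
  list(ratio = (m * N) / (M * n),
       p = unname(test$p.value),
       statistic = unname(test$statistic))
}

#' Structural propensity of phosphosites by annotation category
#'
#' Tallies phosphosites and background residues per level of a categorical
#' annotation (`exposure`, `structure_class` or `disorder`) and reports the
#' E-ratio and chi-squared p-value per level. Missing values are excluded
#' from the tallies; levels absent from the background are skipped with a
#' warning.
#'
#' @param sites Annotated phosphosite data frame.
#' @param background Annotated background-residue data frame.
#' @param category_field Column name of the category.
#' @return Data frame with one row per category level: counts, `e_ratio`,
#'   `p`.
#' @export
propensity_table <- function(sites, background,
                             category_field = c("exposure", "structure_class",
                                                "disorder")) {
  category_field <- match.arg(category_field)
  fg <- sites[[category_field]]
  bg <- background[[category_field]]
  fg <- fg[!is.na(fg)]
  bg <- bg[!is.na(bg)]
  if (length(fg) == 0L || length(bg) == 0L) {
    stop("no non-missing values for category ", category_field)
  }
  M <- length(fg)
  N <- length(bg)
  levels <- sort(unique(c(fg, bg)))
  rows <- lapply(levels, function(lv) {
    n <- sum(bg == lv)
    if (n == 0L) {
      warning("category level '", lv, "' absent from background; skipped")
      return(NULL)
    }
    m <- sum(fg == lv)
    er <- e_ratio(m, M, n, N)
    data.frame(level = lv, m = m, M = M, n = n, N = N,
               e_ratio = er$ratio, p = er$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Count, per (offset, residue), the windows carrying that residue at that
# offset. Matrix of 20 rows (AA20) x length(offsets) columns.
offset_residue_counts <- function(mat, offsets, center) {
  vapply(offsets, function(off) {
    tabulate(factor(mat[, center + off], levels = AA20), nbins = 20L)
  }, integer(20L))
}

#' Greedy motif discovery over fixed-length phosphosite windows
#'
#' Iterative motif-x-style search. At each step the (offset, residue) pair
#' with the smallest exact binomial upper-tail p-value of its foreground
#' occurrence -- given the residue's current background frequency at that
#' offset -- is fixed, and both sets are reduced to the matching windows.
#' Steps stop when no pair attains `p_step` and the occurrence floor. A
#' motif is emitted if its score (the sum of the steps' -log10 p) reaches
#' `min_score` and its final foreground support reaches `min_occ`; its
#' matching foreground windows are then removed and the search repeats.
#'
#' Ties between equally significant steps are broken by smaller offset
#' magnitude, then alphabetical residue.
#'
#' @param fg Foreground peptide windows (common center residue).
#' @param bg Background peptide windows of the same width.
#' @param min_occ Minimum foreground occurrences of a motif (and of any
#'   step).
#' @param min_score Minimum motif score.
#' @param p_step Per-step binomial p-value cutoff.
#' @param max_motifs Safety cap on the number of motifs returned.
#' @return List of `motif_result` objects (possibly empty), each with the
#'   pattern string, score, foreground occurrences and the step table.
#' @export
discover_motifs <- function(fg, bg, min_occ = 10L, min_score = 5,
                            p_step = 1e-4, max_motifs = 10L) {
  if (length(fg) < min_occ) return(list())
  w <- unique(nchar(c(fg, bg)))
  if (length(w) != 1L) stop("foreground and background windows differ in length")
  center <- (w + 1L) %/% 2L
  if (length(unique(substr(fg, center, center))) != 1L) {
    stop("foreground windows must share their center residue")
  }
  offsets <- setdiff(seq_len(w) - center, 0L)

  fg_mat_all <- peptide_matrix(fg)
  bg_mat_all <- peptide_matrix(bg)
  motifs <- list()
  active_fg <- rep(TRUE, nrow(fg_mat_all))

  while (sum(active_fg) >= min_occ && length(motifs) < max_motifs) {
    fg_mat <- fg_mat_all[active_fg, , drop = FALSE]
    bg_mat <- bg_mat_all
    fixed <- NULL   # data.frame(offset, residue, p)

    repeat {
      n_fg <- nrow(fg_mat)
      n_bg <- nrow(bg_mat)
      if (n_fg < min_occ || n_bg == 0L) break
      open <- if (is.null(fixed)) offsets else setdiff(offsets, fixed$offset)
      if (length(open) == 0L) break
      k <- offset_residue_counts(fg_mat, open, center)
      b <- offset_residue_counts(bg_mat, open, center)
      # background probability per (residue, offset); guard zero counts
      p0 <- pmax(b, 0.5) / n_bg
      pval <- pbinom(k - 1L, n_fg, p0, lower.tail = FALSE)
      pval[k < min_occ] <- 1
      if (min(pval) > p_step) break
      cand <- which(pval <= min(pval) + 0, arr.ind = TRUE)
      # tie-break: smaller |offset|, then alphabetical residue
      ord <- order(abs(open[cand[, 2L]]), AA20[cand[, 1L]])
      pick <- cand[ord[1L], ]
      off <- open[pick[2L]]
      res <- AA20[pick[1L]]
      fixed <- rbind(fixed, data.frame(offset = off, residue = res,
                                       p = pval[pick[1L], pick[2L]]))
      fg_mat <- fg_mat[fg_mat[, center + off] == res, , drop = FALSE]
      bg_mat <- bg_mat[bg_mat[, center + off] == res, , drop = FALSE]
    }

    if (is.null(fixed)) break
    score <- sum(-log10(fixed$p))
    if (score >= min_score && nrow(fg_mat) >= min_occ) {
      pattern <- rep(".", w)
      pattern[center] <- substr(fg[1L], center, center)
      pattern[center + fixed$offset] <- fixed$residue
      matched <- motif_matches(fg_mat_all, fixed, center)
      motifs[[length(motifs) + 1L]] <- structure(
        list(pattern = paste(pattern, collapse = ""),
             score = score,
             fg_occurrences = nrow(fg_mat),
             steps = fixed),
        class = "motif_result")
      active_fg <- active_fg & !matched
    } else {
      break
    }
  }
  motifs
}

motif_matches <- function(mat, steps, center) {
  ok <- rep(TRUE, nrow(mat))
  for (i in seq_len(nrow(steps))) {
    ok <- ok & mat[, center + steps$offset[i]] == steps$residue[i]
  }
  ok
}

#' Count windows matching a motif's constraints
#'
#' Direct pattern matching, usable to re-verify a reported motif's support.
#'
#' @param motif A `motif_result`.
#' @param windows Character vector of peptide windows.
#' @return Integer count of matching windows.
#' @export
count_motif_matches <- function(motif, windows) {
  mat <- peptide_matrix(windows)
  center <- (ncol(mat) + 1L) %/% 2L
  sum(motif_matches(mat, motif$steps, center))
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("motif %s  score=%.2f  occurrences=%d  steps=%d\n",
              x$pattern, x$score, x$fg_occurrences, nrow(x$steps)))
  invisible(x)
}

#' Write motif results as TSV
#'
#' @param motifs List of `motif_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  rows <- lapply(motifs, function(m) {
    data.frame(pattern = m$pattern, score = m$score,
               occurrences = m$fg_occurrences,
               steps = paste(sprintf("%s@%+d:%.3g", m$steps$residue,
                                     m$steps$offset, m$steps$p),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = character(), score = numeric(),
               occurrences = integer(), steps = character())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
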