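# Seeded generator of synthetic proteomes with planted N-phosphosites.
#
# The planted sequence signals mirror the qualitative flank patterns seen
# around real sites: K/E enrichment near pHis centers, an S/P-rich stretch
# upstream of pLys, and S/P enrichment on both flanks of pArg. Planted sites
# are biased toward solvent-exposed RSA values while the background spans
# [0, 1], so the negative rule's RSA filter has bite.

#' Configuration of the synthetic proteome generator
#'
#' @param n_proteins Number of proteins.
#' @param length_mean,length_sd,min_length Protein-length law (normal,
#'   rounded, truncated below).
#' @param background Named composition over the 20 canonical amino acids
#'   (sums to 1), or a preset name: `"uniform"` (default; makes planted
#'   enrichment analytically checkable) or `"uniprot"` (Swiss-Prot-like
#'   usage).
#' @param site_counts Named integer vector: planted sites per type.
#' @param effect Named multiplier (>= 1) applied to the signal residues'
#'   background weight at the signal offsets; 1 disables the signal.
#' @param signal_residues,signal_offsets Named lists defining each type's
#'   signal.
#' @param rsa_site_shape Beta shape parameters of planted-site RSA
#'   (exposure-biased; background RSA is uniform on `[0, 1]`).
#' @param structure_probs Background probabilities of helix/sheet/coil.
#' @param site_coil_effect Multiplier on the coil probability for planted
#'   sites.
#' @param p_ordered Probability of the `ordered` disorder label.
#' @param seed Seed; fixed seed implies fully deterministic output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 2600L,
                              length_mean = 400, length_sd = 80,
                              min_length = 60L,
                              background = "uniform",
                              site_counts = c(pHis = 2000L, pLys = 4000L,
                                              pArg = 2800L),
                              effect = c(pHis = 5, pLys = 5, pArg = 5),
                              signal_residues = list(pHis = c("K", "E"),
                                                     pLys = c("S", "P"),
                                                     pArg = c("S", "P")),
                              signal_offsets = list(pHis = c(-7:-1, 1:7),
                                                    pLys = -8:-1,
                                                    pArg = c(-4:-1, 1:4)),
                              rsa_site_shape = c(5, 3),
                              structure_probs = c(helix = 0.30, sheet = 0.20,
                                                  coil = 0.50),
                              site_coil_effect = 1,
                              p_ordered = 0.7,
                              seed = 1L) {
  if (is.character(background)) {
    background <- switch(match.arg(background, c("uniform", "uniprot")),
                         uniform = setNames(rep(1 / 20, 20L), AA20),
                         uniprot = uniprot_composition())
  }
  stopifnot(setequal(names(background), AA20),
            abs(sum(background) - 1) < 1e-8,
            all(effect >= 1),
            setequal(names(site_counts), names(SITE_RESIDUES)),
            all(site_counts >= 0))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_mean = length_mean, length_sd = length_sd,
                 min_length = as.integer(min_length),
                 background = background[AA20],
                 site_counts = site_counts,
                 effect = effect,
                 signal_residues = signal_residues,
                 signal_offsets = signal_offsets,
                 rsa_site_shape = rsa_site_shape,
                 structure_probs = structure_probs,
                 site_coil_effect = site_coil_effect,
                 p_ordered = p_ordered,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Swiss-Prot-like residue usage.
uniprot_composition <- function() {
  comp <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
            Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
            L = 0.0966, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0473,
            S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)
  comp <- comp / sum(comp)
  comp[AA20]
}

exposure_label <- function(rsa) {
  ifelse(rsa >= 0.25, "exposed", ifelse(rsa <= 0.10, "buried",
                                        "intermediate"))
}

#' Generate a synthetic proteome with planted N-phosphosites
#'
#' Sequences are drawn i.i.d. from the background composition. Planted
#' positive sites get their center letter set to the type's residue and
#' their flank letters at the signal offsets resampled from the
#' enrichment-weighted composition; all other residues are untouched.
#' Per-residue RSA is uniform on `[0, 1]` except at planted sites, which
#' draw from the exposure-biased Beta law. Planted centers are at least 16
#' residues from the termini and separated by at least 31 residues within a
#' protein, so windows and signals do not collide.
#'
#' @param cfg A [simulation_config()].
#' @return A `synthetic_proteome` list: `proteins` (data frame), `sites`
#'   (annotation data frame with `rsa`, `structure_class`, `disorder`,
#'   `exposure`), `rsa` (named list of per-residue vectors) and `config`.
#' @export
generate_proteome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  len <- pmax(cfg$min_length, round(rnorm(n, cfg$length_mean, cfg$length_sd)))
  ids <- sprintf("SYN%05d", seq_len(n))
  seqs <- lapply(len, function(L) sample(AA20, L, replace = TRUE,
                                         prob = cfg$background))

  half <- 15L
  occupied <- vector("list", n)  # planted centers per protein
  site_rows <- vector("list", sum(cfg$site_counts))
  row_i <- 0L
  weight <- pmax(len - 2L * half, 0L)
  for (ty in names(cfg$site_counts)) {
    letter <- SITE_RESIDUES[[ty]]
    sig_res <- cfg$signal_residues[[ty]]
    offs <- cfg$signal_offsets[[ty]]
    w_sig <- cfg$background
    w_sig[sig_res] <- w_sig[sig_res] * cfg$effect[[ty]]
    w_sig <- w_sig / sum(w_sig)
    planted <- 0L
    tries <- 0L
    while (planted < cfg$site_counts[[ty]] && tries < cfg$site_counts[[ty]] * 50L) {
      tries <- tries + 1L
      i <- sample.int(n, 1L, prob = weight)
      pos <- sample.int(len[i] - 2L * half, 1L) + half
      if (length(occupied[[i]]) &&
          any(abs(occupied[[i]] - pos) < 31L)) next
      occupied[[i]] <- c(occupied[[i]], pos)
      seqs[[i]][pos] <- letter
      seqs[[i]][pos + offs] <- sample(AA20, length(offs), replace = TRUE,
                                      prob = w_sig)
      planted <- planted + 1L
      row_i <- row_i + 1L
      site_rows[[row_i]] <- data.frame(protein_id = ids[i], position = pos,
                                       residue = letter, site_type = ty,
                                       stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows[seq_len(row_i)])

  rsa <- lapply(len, runif)
  names(rsa) <- ids
  sites$rsa <- rbeta(nrow(sites), cfg$rsa_site_shape[1L],
                     cfg$rsa_site_shape[2L])
  for (j in seq_len(nrow(sites))) {
    rsa[[sites$protein_id[j]]][sites$position[j]] <- sites$rsa[j]
  }

  p_struct <- cfg$structure_probs
  p_site <- p_struct * c(helix = 1, sheet = 1, coil = cfg$site_coil_effect)
  p_site <- p_site / sum(p_site)
  sites$structure_class <- sample(names(p_site), nrow(sites), replace = TRUE,
                                  prob = p_site)
  sites$disorder <- sample(c("ordered", "disordered"), nrow(sites),
                           replace = TRUE,
                           prob = c(cfg$p_ordered, 1 - cfg$p_ordered))
  sites$exposure <- exposure_label(sites$rsa)
  sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
  rownames(sites) <- NULL

  proteins <- data.frame(id = ids,
                         sequence = vapply(seqs, paste, "", collapse = ""),
                         stringsAsFactors = FALSE)
  structure(list(proteins = proteins, sites = sites, rsa = rsa,
                 config = cfg),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat("Synthetic proteome:", nrow(x$proteins), "proteins,",
      sum(nchar(x$proteins$sequence)), "residues,",
      nrow(x$sites), "planted sites",
      sprintf("(seed %d)\n", x$config$seed))
  invisible(x)
}

#' Sample annotated background residues from a synthetic proteome
#'
#' Non-planted H/K/R residues with their RSA values and background-law
#' structural labels, usable as the background of propensity analyses.
#'
#' @param proteome A `synthetic_proteome`.
#' @param n Number of residues to sample.
#' @param seed Seed (defaults to the proteome's seed plus one).
#' @return Annotation data frame in the same layout as `proteome$sites`.
#' @export
background_annotations <- function(proteome, n = 5000L,
                                   seed = proteome$config$seed + 1L) {
  set.seed(seed)
  cfg <- proteome$config
  prot <- proteome$proteins
  site_key <- paste(proteome$sites$protein_id, proteome$sites$position)
  pool <- do.call(rbind, lapply(seq_len(nrow(prot)), function(i) {
    chars <- strsplit(prot$sequence[i], "", fixed = TRUE)[[1L]]
    pos <- which(chars %in% SITE_RESIDUES)
    data.frame(protein_id = prot$id[i], position = pos, residue = chars[pos],
               stringsAsFactors = FALSE)
  }))
  pool <- pool[!(paste(pool$protein_id, pool$position) %in% site_key), ,
               drop = FALSE]
  pool <- pool[sample.int(nrow(pool), min(n, nrow(pool))), , drop = FALSE]
  pool$site_type <- site_type_of(pool$residue)
  pool$rsa <- lookup_rsa(proteome$rsa, pool$protein_id, pool$position)
  pool$structure_class <- sample(names(cfg$structure_probs), nrow(pool),
                                 replace = TRUE, prob = cfg$structure_probs)
  pool$disorder <- sample(c("ordered", "disordered"), nrow(pool),
                          replace = TRUE,
                          prob = c(cfg$p_ordered, 1 - cfg$p_ordered))
  pool$exposure <- exposure_label(pool$rsa)
  rownames(pool) <- NULL
  pool
}

#' Build per-type benchmarks from a synthetic proteome
#'
#' Positives come from the planted sites; negatives follow the four-step
#' negative rule on the same annotations (same proteins, RSA ceilings,
#' identity filter against the positives).
#'
#' @param proteome A `synthetic_proteome` (or a `simulation_config`, which
#'   is generated first).
#' @param types Site types to build.
#' @param negative_cfg A [negative_config()].
#' @param w Window width.
#' @return Named list of example data frames, one per type, with a
#'   `summary` attribute from [benchmark_summary()].
#' @export
make_benchmark <- function(proteome, types = c("pHis", "pLys", "pArg"),
                           negative_cfg = negative_config(), w = 31L) {
  if (inherits(proteome, "simulation_config")) {
    proteome <- generate_proteome(proteome)
  }
  stopifnot(inherits(proteome, "synthetic_proteome"))
  positives <- build_positives(proteome$sites, proteome$proteins, w = w)
  negatives <- build_negatives(proteome$proteins, proteome$sites,
                               proteome$rsa, cfg = negative_cfg,
                               positives = positives, types = types, w = w)
  out <- lapply(setNames(types, types), function(ty) {
    benchmark_examples(positives, negatives, ty)
  })
  attr(out, "summary") <- benchmark_summary(out)
  out
}
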