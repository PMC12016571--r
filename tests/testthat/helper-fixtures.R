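# Shared fixtures: tiny synthetic scenes, brute-force oracles, cached models.

.fixture_env <- new.env()

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_window <- function(n = 1L, w = 31L, center = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    chars <- sample(AA_LETTERS, w, replace = TRUE)
    if (!is.null(center)) chars[(w + 1L) %/% 2L] <- center
    paste(chars, collapse = "")
  }, "")
  out
}

tiny_config <- function(...) {
  simulation_config(n_proteins = 60L, length_mean = 220, length_sd = 30,
                    site_counts = c(pHis = 80L, pLys = 100L, pArg = 80L),
                    seed = 11L, ...)
}

tiny_benchmark <- function() {
  if (is.null(.fixture_env$bench)) {
    .fixture_env$bench <- make_benchmark(generate_proteome(tiny_config()))
  }
  .fixture_env$bench
}

toy_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    ex <- tiny_benchmark()$pHis
    .fixture_env$bundle <- train_model(ex, "pHis", nrounds = 60L, seed = 4L)
  }
  .fixture_env$bundle
}

# Independent confusion-metric oracle: reconstructs label/prediction vectors
# and measures each quantity by counting; MCC is the Pearson correlation of
# the two binary vectors.
brute_confusion_metrics <- function(tp, fp, tn, fn) {
  y <- c(rep(1L, tp + fn), rep(0L, tn + fp))
  p <- c(rep(1L, tp), rep(0L, fn), rep(0L, tn), rep(1L, fp))
  prop <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  sens <- prop(p[y == 1L] == 1L)
  spec <- prop(p[y == 0L] == 0L)
  prec <- prop(y[p == 1L] == 1L)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  acc <- mean(y == p)
  mcc <- suppressWarnings(stats::cor(y, p))
  if (!is.na(mcc) && is.nan(mcc)) mcc <- NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    accuracy = acc, mcc = mcc)
}

# Brute-force homology oracle: per candidate, max ungapped identity to any
# positive (matching non-pad positions / window length), via a double loop.
brute_identity_keep <- function(candidates, positives, threshold = 0.30) {
  w <- nchar(candidates[1L])
  cs <- strsplit(candidates, "", fixed = TRUE)
  ps <- strsplit(positives, "", fixed = TRUE)
  vapply(cs, function(a) {
    for (b in ps) {
      ident <- sum(a == b & a != "-") / w
      if (ident >= threshold - 1e-12) return(FALSE)
    }
    TRUE
  }, logical(1L))
}
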