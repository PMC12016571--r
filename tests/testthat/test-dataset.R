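test_that("positive construction collapses identical windows across proteins", {
  core <- paste0(strrep("A", 15), "H", strrep("C", 15))
  prot <- data.frame(
    id = c("P1", "P2", "P3"),
    sequence = c(paste0("GG", core, "GG"), paste0("WW", core, "WW"),
                 paste0("GG", gsub("C", "D", core), "GG")),
    stringsAsFactors = FALSE
  )
  sites <- data.frame(protein_id = c("P1", "P2", "P3"), position = 18L,
                      residue = "H", stringsAsFactors = FALSE)
  pos <- build_positives(sites, prot)
  # P1 and P2 carry the identical 31-mer; P3 differs
  expect_equal(nrow(pos), 2L)
  expect_true(all(pos$label == 1L))
  expect_equal(attr(pos, "summary")$pHis[["n_windows"]], 2)

  bad <- transform(sites, residue = "K")
  expect_error(build_positives(bad, prot), "does not match")
})

test_that("distinct windows produce one example each", {
  set.seed(8)
  prot <- data.frame(id = sprintf("P%d", 1:5),
                     sequence = random_window(5, w = 61),
                     stringsAsFactors = FALSE)
  # force an H at position 31 of each (distinct flanks)
  substr(prot$sequence, 31, 31) <- "H"
  sites <- data.frame(protein_id = prot$id, position = 31L, residue = "H",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(build_positives(sites, prot)), 5L)
})

test_that("the negative rule enforces RSA ceilings and excludes positives", {
  set.seed(21)
  seqc <- random_window(1, w = 120)
  chars <- strsplit(seqc, "")[[1]]
  chars[c(20, 50, 80, 100)] <- "H"
  prot <- data.frame(id = "P1", sequence = paste(chars, collapse = ""),
                     stringsAsFactors = FALSE)
  sites <- data.frame(protein_id = "P1", position = 20L, residue = "H",
                      stringsAsFactors = FALSE)
  rsa <- list(P1 = rep(0.5, 120))     # everything exposed
  rsa$P1[50] <- 0.10                  # one buried His candidate
  rsa$P1[80] <- NA                    # missing RSA: skipped, not fatal
  neg <- build_negatives(prot, sites, rsa)
  expect_equal(neg$position, 50L)     # 100 is exposed (0.5 > 0.12); 20 is a site
  expect_true(all(neg$rsa <= 0.12))
  expect_equal(attr(neg, "n_missing_rsa"), 1L)
})

test_that("homology filtering removes candidates at or above the threshold", {
  set.seed(5)
  positives <- random_window(30, seed = 5)
  # candidate identical to a positive is removed at any threshold <= 1
  expect_false(homology_filter(positives[1], positives)[1])
  # candidate agreeing in exactly 9/31 positions (~0.29) is kept at 0.30
  pos1 <- strsplit(positives[1], "")[[1]]
  cand9 <- pos1
  repl <- setdiff(AA_LETTERS, pos1)
  cand9[10:31] <- rep_len(repl, 22)   # differs at 22 positions, matches 9
  expect_equal(sum(cand9 == pos1), 9L)
  cand9 <- paste(cand9, collapse = "")
  others <- random_window(50, seed = 6)
  keep <- homology_filter(c(cand9, others), positives)
  expect_true(keep[1])
  # 10/31 (~0.32) is removed
  cand10 <- pos1
  cand10[11:31] <- rep_len(repl, 21)
  cand10 <- paste(cand10, collapse = "")
  expect_false(homology_filter(cand10, positives))
  # vacuous filter
  expect_true(all(homology_filter(others, character(0))))
})

test_that("homology filtering agrees with the brute-force all-pairs oracle", {
  set.seed(31)
  positives <- random_window(60, seed = 31)
  cands <- random_window(60, seed = 32)
  # inject near-duplicates at varying identity
  for (i in 1:10) {
    p <- strsplit(positives[i], "")[[1]]
    k <- sample(0:25, 1)
    if (k > 0) p[sample(31, k)] <- sample(AA_LETTERS, k, replace = TRUE)
    cands[i] <- paste(p, collapse = "")
  }
  expect_identical(homology_filter(cands, positives),
                   brute_identity_keep(cands, positives))
  # shared pad runs never count as matches: non-pad parts disjoint => kept
  padded_pos <- paste0(strrep("-", 21), strrep("W", 10))
  padded_cand <- paste0(strrep("-", 21), strrep("G", 10))
  expect_true(homology_filter(padded_cand, padded_pos))
})

test_that("splits are stratified, exhaustive and reproducible", {
  labels <- c(rep(1L, 40), rep(0L, 120))
  plan <- split_plan(n_repeats = 3, k_folds = 10, seed = 77)
  sp <- split_dataset(labels, plan)
  expect_length(sp, 3L)
  for (r in sp) {
    expect_equal(sort(c(r$train, r$test)), seq_along(labels))
    expect_length(r$train, 128L)  # 0.8 * 160, stratified 32 + 96
    expect_equal(sum(labels[r$train] == 1L), 32L)
    expect_equal(sort(unlist(r$folds)), sort(r$train))
    # class ratio preserved within one example per fold
    n_pos_train <- sum(labels[r$train] == 1L)
    for (f in r$folds) {
      expect_lte(abs(sum(labels[f] == 1L) - n_pos_train / 10), 1)
      expect_lte(abs(sum(labels[f] == 0L) - (128 - n_pos_train) / 10), 1)
    }
  }
  expect_identical(sp, split_dataset(labels, plan))
  expect_error(split_dataset(rep(1L, 10), plan), "class")

  # folding the full 40/120 set at k = 10 gives exactly 4 + 12 per fold
  set.seed(1)
  fold_id <- npsite:::stratified_folds(labels, 10L)
  tab <- table(fold_id, labels)
  expect_true(all(tab[, "1"] == 4L))
  expect_true(all(tab[, "0"] == 12L))
})

test_that("benchmark writers emit deterministic text artifacts", {
  bench <- tiny_benchmark()
  d <- withr::local_tempdir()
  paths <- write_benchmark(bench$pHis, file.path(d, "phis"))
  expect_true(all(file.exists(paths)))
  fasta_back <- read_fasta(paths[["fasta"]], alphabet = "peptide")
  expect_equal(nrow(fasta_back), nrow(bench$pHis))
  sp <- split_dataset(bench$pHis$label, split_plan(n_repeats = 1, seed = 3))
  jp <- write_splits(sp, file.path(d, "splits.json"))
  expect_true(file.exists(jp))
  expect_equal(length(jsonlite::read_json(jp)), 1L)
})
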