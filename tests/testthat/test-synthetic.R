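test_that("generation is byte-identical under a fixed seed", {
  a <- generate_proteome(tiny_config())
  b <- generate_proteome(tiny_config())
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$sites, b$sites)
  expect_identical(a$rsa, b$rsa)
})

test_that("planted sites sit on their residue with in-range positions", {
  pt <- generate_proteome(tiny_config())
  expect_silent(validate_sites(pt$sites, pt$proteins))
  expect_true(all(pt$sites$residue ==
                  c(pHis = "H", pLys = "K", pArg = "R")[pt$sites$site_type]))
  len <- nchar(pt$proteins$sequence)[match(pt$sites$protein_id,
                                           pt$proteins$id)]
  expect_true(all(pt$sites$position >= 16 & pt$sites$position <= len - 15))
})

test_that("background composition is recoverable at scale", {
  cfg <- simulation_config(n_proteins = 500L, length_mean = 220,
                           length_sd = 20,
                           site_counts = c(pHis = 10L, pLys = 10L,
                                           pArg = 10L),
                           seed = 23L)
  pt <- generate_proteome(cfg)
  chars <- unlist(strsplit(pt$proteins$sequence, ""), use.names = FALSE)
  expect_gt(length(chars), 100000L)
  freq <- table(factor(chars, levels = AA_LETTERS)) / length(chars)
  expect_true(all(abs(freq - 1 / 20) < 0.01))
})

test_that("a unit effect multiplier leaves flank composition at background", {
  cfg <- simulation_config(n_proteins = 200L, length_mean = 250,
                           length_sd = 30,
                           site_counts = c(pHis = 400L, pLys = 10L,
                                           pArg = 10L),
                           effect = c(pHis = 1, pLys = 1, pArg = 1),
                           seed = 101L)
  pt <- generate_proteome(cfg)
  win <- extract_windows(pt$proteins,
                         pt$sites[pt$sites$site_type == "pHis", ])
  offs <- cfg$signal_offsets$pHis
  mat <- do.call(rbind, strsplit(win$peptide, ""))
  flank <- as.vector(mat[, 16 + offs])
  expect_gt(length(flank), 5000L)
  counts <- table(factor(flank, levels = AA_LETTERS))
  test <- chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(test$p.value, 0.01)
})

test_that("the planted enrichment is visible at the signal offsets", {
  cfg <- simulation_config(n_proteins = 250L, length_mean = 250,
                           length_sd = 30,
                           site_counts = c(pHis = 10L, pLys = 500L,
                                           pArg = 10L),
                           effect = c(pHis = 1, pLys = 4, pArg = 1),
                           signal_offsets = list(pHis = c(-7:-1, 1:7),
                                                 pLys = -4:-1,
                                                 pArg = c(-4:-1, 1:4)),
                           seed = 57L)
  pt <- generate_proteome(cfg)
  win <- extract_windows(pt$proteins,
                         pt$sites[pt$sites$site_type == "pLys", ])
  mat <- do.call(rbind, strsplit(win$peptide, ""))
  sig <- as.vector(mat[, 16 + (-4:-1)])
  sp_freq <- mean(sig %in% c("S", "P"))
  background_sp <- 2 / 20
  expect_gte(sp_freq, 2 * background_sp)
})

test_that("benchmarks built on generator output honor the pipeline contracts", {
  bench <- tiny_benchmark()
  thr <- c(pHis = 0.12, pLys = 0.30, pArg = 0.20)
  for (ty in names(bench)) {
    ex <- bench[[ty]]
    neg <- ex[ex$label == 0, ]
    expect_true(all(neg$rsa <= thr[[ty]]))
    both <- intersect(ex$peptide[ex$label == 1], ex$peptide[ex$label == 0])
    expect_length(both, 0L)
    expect_false(any(duplicated(ex$peptide[ex$label == 0])))
  }
  summ <- attr(bench, "summary")
  expect_equal(summ$ratio,
               round(summ$n_negative / summ$n_positive, 2))
})

test_that("generator artifacts feed the downstream modules without adapters", {
  pt <- generate_proteome(tiny_config())
  d <- withr::local_tempdir()
  fp <- write_fasta(pt$proteins, file.path(d, "prot.fasta"))
  sp <- write_sites(pt$sites, file.path(d, "sites.tsv"))
  prot <- read_fasta(fp)
  sites <- read_sites(sp)
  expect_identical(prot$sequence, pt$proteins$sequence)
  pos <- build_positives(sites, prot)
  expect_gt(nrow(pos), 0L)
})
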