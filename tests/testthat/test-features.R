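test_that("AAC encodes frequencies over canonical residues", {
  homo <- strrep("A", 31)
  v <- encode_aac(homo)
  expect_equal(unname(v[1, "AAC_A"]), 1)
  expect_equal(sum(v), 1)

  # hand count: A appears at positions 1 and 21 of this 31-mer
  pep <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLM"
  v <- encode_aac(pep)
  expect_equal(unname(v[1, "AAC_A"]), 2 / 31)
  expect_equal(sum(v), 1, tolerance = 1e-12)

  # pads excluded from numerator and denominator
  padded <- paste0(strrep("-", 10), strrep("G", 21))
  v <- encode_aac(padded)
  expect_equal(unname(v[1, "AAC_G"]), 1)
  expect_error(encode_aac(strrep("-", 31)), "no canonical residue")
})

test_that("AAC is permutation-invariant; positional encoders are not", {
  pep <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLM"
  swapped <- paste0("C", "A", substr(pep, 3, 31))  # swap unequal residues
  expect_equal(encode_aac(pep)[1, ], encode_aac(swapped)[1, ])
  expect_false(all(encode_hqi8(pep)[1, ] == encode_hqi8(swapped)[1, ]))
  expect_false(all(encode_blosum62(pep)[1, ] == encode_blosum62(swapped)[1, ]))
})

test_that("HQI8 layout is position-major with zero pad blocks", {
  tab <- hqi8_table()
  expect_equal(dim(tab), c(20L, 8L))
  expect_false(anyNA(tab))

  homo <- strrep("G", 31)
  v <- encode_hqi8(homo)
  expect_equal(ncol(v), 248L)
  expect_equal(unname(matrix(v, nrow = 31, byrow = TRUE)),
               matrix(rep(tab["G", ], 31), nrow = 31, byrow = TRUE),
               ignore_attr = TRUE)

  padded <- paste0("-", strrep("A", 30))
  v <- encode_hqi8(padded)
  expect_equal(unname(v[1, 1:8]), rep(0, 8))
})

test_that("HQI8 values match the AAindex source for a spot-checked index", {
  # BLAM930101 alanine value as published in AAindex
  tab <- hqi8_table()
  expect_equal(unname(tab["A", "BLAM930101"]), 0.96)
  expect_equal(unname(tab["P", "BLAM930101"]), -2.50)
})

test_that("BLOSUM62 encoding uses per-position substitution rows", {
  m <- blosum62_matrix()
  expect_equal(dim(m), c(21L, 20L))
  # canonical submatrix symmetric, positive diagonal
  sub <- m[AA_LETTERS, AA_LETTERS]
  expect_true(isSymmetric(unname(sub)))
  expect_true(all(diag(sub) > 0))

  homo <- strrep("A", 31)
  v <- encode_blosum62(homo)
  expect_equal(ncol(v), 620L)
  expect_equal(unname(v[1, 1:20]), unname(m["A", ]))

  # center letter W: component at (15*20 + column of W) is the W-W score
  pep <- paste0(strrep("A", 15), "W", strrep("A", 15))
  v <- encode_blosum62(pep)
  w_col <- which(colnames(v) == "B62_p16_W")
  expect_equal(w_col, 15L * 20L + which(AA_LETTERS == "W"))
  expect_equal(unname(v[1, w_col]), 11)  # published BLOSUM62 W-W score

  # pad row equals the X/any row
  pad <- paste0("-", strrep("A", 30))
  amb <- paste0("X", strrep("A", 30))
  expect_equal(encode_blosum62(pad)[1, 1:20], encode_blosum62(amb)[1, 1:20])
})

test_that("the shipped NCBI-format matrix file agrees with the package default", {
  path <- system.file("extdata", "BLOSUM62.txt", package = "npsite")
  parsed <- read_blosum(path)
  expect_equal(blosum62_matrix(parsed), blosum62_matrix())
})

test_that("combinations concatenate in fixed order with the seven lengths", {
  pep <- random_window(3, seed = 9)
  expect_equal(ncol(encode_windows(pep, c("AAC", "HQI8"))), 268L)
  expect_equal(ncol(encode_windows(pep, c("HQI8", "BLOSUM62"))), 868L)
  expect_equal(ncol(encode_windows(pep, c("AAC", "BLOSUM62"))), 640L)
  expect_equal(ncol(encode_windows(pep)), 888L)
  # single-set combo is the identity
  expect_equal(encode_windows(pep, "BLOSUM62"), encode_blosum62(pep),
               ignore_attr = TRUE)
  # order of request does not matter; layout order is fixed
  a <- encode_windows(pep, c("BLOSUM62", "AAC"))
  b <- encode_windows(pep, c("AAC", "BLOSUM62"))
  expect_identical(a, b)
  expect_error(encode_windows(pep, character()))
})

test_that("encoding is deterministic and feature names are unique", {
  pep <- random_window(2, seed = 13)
  a <- encode_windows(pep)
  b <- encode_windows(pep)
  expect_identical(a, b)
  expect_false(anyDuplicated(colnames(a)) > 0)
})
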