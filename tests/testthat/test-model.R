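test_that("a separable toy problem is learned perfectly", {
  pos <- vapply(1:30, function(i) {
    p <- strsplit(random_window(1, center = "K", seed = i), "")[[1]]
    p[c(5:12, 20:27)] <- "K"
    paste(p, collapse = "")
  }, "")
  neg <- vapply(31:60, function(i) {
    p <- strsplit(random_window(1, center = "K", seed = i), "")[[1]]
    p[c(5:12, 20:27)] <- "A"
    paste(p, collapse = "")
  }, "")
  ex <- data.frame(peptide = c(pos, neg), label = rep(1:0, each = 30),
                   stringsAsFactors = FALSE)
  b <- train_model(ex, "pLys", nrounds = 40L, seed = 2L)
  prob <- predict(b, ex)
  acc <- mean((prob > 0.5) == ex$label)
  expect_equal(acc, 1)
  expect_error(train_model(ex[ex$label == 1, ], "pLys"), "both classes")
})

test_that("training and repeated evaluation are deterministic under a seed", {
  ex <- tiny_benchmark()$pHis
  b1 <- train_model(ex, "pHis", nrounds = 30L, seed = 9L)
  b2 <- train_model(ex, "pHis", nrounds = 30L, seed = 9L)
  expect_identical(predict(b1, ex), predict(b2, ex))
  plan <- split_plan(n_repeats = 2, seed = 42)
  r1 <- evaluate_repeated(ex, "pHis", plan, nrounds = 30L)
  r2 <- evaluate_repeated(ex, "pHis", plan, nrounds = 30L)
  expect_identical(r1$raw, r2$raw)
})

test_that("repeated evaluation reports seven metrics with sd semantics", {
  ex <- tiny_benchmark()$pHis
  rep1 <- evaluate_repeated(ex, "pHis", split_plan(n_repeats = 1, seed = 3),
                            nrounds = 30L)
  expect_setequal(names(rep1$mean),
                  c("sensitivity", "specificity", "precision", "f1",
                    "accuracy", "mcc", "auc"))
  expect_true(all(rep1$sd == 0))
  rep2 <- evaluate_repeated(ex, "pHis", split_plan(n_repeats = 2, seed = 3),
                            nrounds = 30L)
  expect_equal(rep2$n_repeats, 2L)
})

test_that("cross-validation pools one out-of-fold prediction per example", {
  ex <- tiny_benchmark()$pHis
  # minimal stratified case: k = 2
  cv <- cross_validate(ex, "pHis", k = 2L, repeats = 1L, seed = 5L,
                       nrounds = 20L)
  expect_s3_class(cv, "metrics_report")
  expect_false(anyNA(cv$mean[c("accuracy", "auc")]))
  expect_error(cross_validate(ex[c(1:4, 100:180), ], "pHis", k = 10L,
                              repeats = 1L, nrounds = 20L), "folds")
})

test_that("default per-type combinations follow the model-selection result", {
  expect_equal(default_combo("pHis"), c("AAC", "HQI8"))
  expect_equal(default_combo("pLys"), c("AAC", "HQI8", "BLOSUM62"))
  expect_equal(default_combo("pArg"), c("AAC", "HQI8"))
  ex <- tiny_benchmark()$pHis
  b <- train_model(ex, "pHis", nrounds = 10L, seed = 1L)
  expect_equal(length(b$feature_names), 268L)
})

test_that("bundles round-trip through disk with version protection", {
  b <- toy_bundle()
  ex <- tiny_benchmark()$pHis
  f <- withr::local_tempfile(fileext = ".bundle")
  save_bundle(b, f)
  back <- load_bundle(f)
  expect_equal(predict(back, ex), predict(b, ex), tolerance = 1e-12)
  expect_equal(back$combo, b$combo)
  expect_equal(back$fingerprint$md5, b$fingerprint$md5)
  # incompatible major version refuses to load
  obj <- readRDS(f)
  obj$version <- "99.0.0"
  saveRDS(obj, f)
  expect_error(load_bundle(f), "incompatible")
})

test_that("hyperparameter grids are selected by cross-validated AUC", {
  ex <- tiny_benchmark()$pHis
  grid <- data.frame(nrounds = c(5L, 30L), max_depth = c(1L, 4L),
                     eta = c(0.3, 0.1))
  b <- train_model(ex, "pHis", hyper_grid = grid, cv_folds = 3L, seed = 8L)
  expect_true(b$nrounds %in% grid$nrounds)
  expect_true(b$params$max_depth %in% grid$max_depth)
})

test_that("held-out AUC increases with the planted effect size", {
  aucs <- vapply(c(1, 2.5, 5), function(eff) {
    cfg <- simulation_config(n_proteins = 250L, length_mean = 300,
                             length_sd = 30,
                             site_counts = c(pHis = 400L, pLys = 10L,
                                             pArg = 10L),
                             effect = c(pHis = eff, pLys = 1, pArg = 1),
                             seed = 91L)
    bench <- make_benchmark(generate_proteome(cfg), types = "pHis")
    ex <- bench$pHis
    sp <- split_dataset(ex$label, split_plan(n_repeats = 1, seed = 17))[[1]]
    b <- train_model(ex[sp$train, ], "pHis", nrounds = 150L, seed = 17L)
    auc_score(ex$label[sp$test], predict(b, ex[sp$test, ]))
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_lt(aucs[1], 0.65)  # no signal: near chance
  expect_gt(aucs[3], 0.80)
})
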