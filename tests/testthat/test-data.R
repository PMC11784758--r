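test_that("ordinal-dialect files parse with missing-value handling", {
  f <- write_wbcd_fixture(tempfile(fileext = ".data"))
  raw <- load_uci(f, "wbcd")
  expect_equal(nrow(raw$data), 3)
  expect_named(raw$data, gmvo:::wbcd_columns)
  expect_false(anyNA(raw$data))

  # '?' is flagged missing, not parsed as a number
  f2 <- write_wbcd_fixture(tempfile(), rows = c(
    "1,5,1,1,1,2,?,3,1,1,2",
    "2,5,4,4,5,7,1,3,2,1,2",
    "3,3,1,1,1,2,3,3,1,1,4"
  ))
  raw2 <- load_uci(f2, "wbcd")
  expect_true(is.na(raw2$data$bare_nuclei[1]))
  expect_type(raw2$data$bare_nuclei, "integer")

  expect_error(load_uci(tempfile("nope"), "wbcd"), "cannot read")
  # wrong column count is a malformed-file error
  f3 <- tempfile()
  writeLines("1,2,3,4", f3)
  expect_error(load_uci(f3, "wbcd"), "malformed")
  f4 <- tempfile()
  writeLines(paste(rep("1", 31), collapse = ","), f4)
  expect_error(load_uci(f4, "wdbc"), "malformed")
  unlink(c(f, f2, f3, f4))
})

test_that("preprocessing imputes, encodes and selects features", {
  # mean imputation over observed values: '?' among {1, 3} becomes 2
  f <- write_wbcd_fixture(tempfile(), rows = c(
    "1,5,1,1,1,2,?,3,1,1,2",
    "2,5,4,4,5,7,1,3,2,1,2",
    "3,3,1,1,1,2,3,3,1,1,4"
  ))
  ds <- load_uci(f, "wbcd") |> preprocess_raw()
  expect_equal(unname(ds$X[1, "bare_nuclei"]), 2)
  expect_false(anyNA(ds$X))
  expect_identical(ds$y, c(0L, 0L, 1L))
  expect_equal(ncol(ds$X), 9)
  expect_equal(ds$provenance, "WBCD")

  # an explicit imputation value (train-only fitting) overrides the mean
  ds2 <- preprocess_raw(load_uci(f, "wbcd"), impute_value = 7)
  expect_equal(unname(ds2$X[1, "bare_nuclei"]), 7)

  # all-malignant labels map to all ones
  f2 <- write_wbcd_fixture(tempfile(), rows = c(
    "1,5,1,1,1,2,1,3,1,1,4",
    "2,5,4,4,5,7,1,3,2,1,4"
  ))
  expect_identical(preprocess_raw(load_uci(f2, "wbcd"))$y, c(1L, 1L))

  # unknown labels are reported with the offending value
  f3 <- write_wbcd_fixture(tempfile(), rows = c("1,5,1,1,1,2,1,3,1,1,9"))
  expect_error(preprocess_raw(load_uci(f3, "wbcd")), "9")
  unlink(c(f, f2, f3))
})

test_that("continuous dialect keeps exactly the 17 retained features", {
  f <- write_wdbc_fixture(tempfile())
  ds <- preprocess_raw(load_uci(f, "wdbc"))
  expect_equal(ncol(ds$X), 17)
  expect_identical(colnames(ds$X), wdbc_feature_subset())
  expect_identical(sort(unique(ds$y)), c(0L, 1L))
  # 'N' is accepted as a benign synonym of 'B'
  lines <- readLines(f)
  lines[1] <- sub(",B,", ",N,", lines[1])
  writeLines(lines, f)
  ds2 <- preprocess_raw(load_uci(f, "wdbc"))
  expect_equal(ds2$y[1], 0L)
  unlink(f)
})

test_that("preprocessing is idempotent through a save/load cycle", {
  ds <- generate_synthetic(synthetic_config(n_samples = 60, ordinal = TRUE,
                                            missing_rate = 0.1, seed = 2))
  f <- tempfile()
  df <- ds$raw$data
  df$bare_nuclei <- ifelse(is.na(df$bare_nuclei), "?", df$bare_nuclei)
  write.table(df, f, sep = ",", col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  d1 <- preprocess_raw(load_uci(f, "wbcd"))
  expect_false(anyNA(d1$X))
  expect_equal(nrow(d1$X), 60)
  unlink(f)
})

test_that("min-max normalization fits on train and passes test through", {
  tr <- gmvo:::new_bc_dataset(matrix(c(1, 10, 5, 5), 2, 2), c(0, 1),
                              c("a", "b"), "synthetic")
  te <- gmvo:::new_bc_dataset(matrix(c(20, -3, 7, 5), 2, 2), c(0, 1),
                              c("a", "b"), "synthetic")
  nm <- minmax_fit_apply(tr, list(te))
  expect_equal(unname(nm$train$X[, 1]), c(0, 1))
  # constant feature maps to zero
  expect_equal(unname(nm$train$X[, 2]), c(0, 0))
  # test values outside the train range pass through beyond [0, 1]
  expect_gt(nm$others[[1]]$X[1, 1], 1)
  expect_lt(nm$others[[1]]$X[2, 1], 0)
  expect_equal(nm$ranges$min, c(1, 5))
  expect_equal(nm$ranges$max, c(10, 5))

  # denormalization with the stored statistics recovers training features
  ds <- generate_synthetic(synthetic_config(n_samples = 50, seed = 3))
  orig <- ds$X
  nm2 <- minmax_fit_apply(ds)
  span <- nm2$ranges$max - nm2$ranges$min
  back <- sweep(sweep(nm2$train$X, 2, span, `*`), 2, nm2$ranges$min, `+`)
  expect_equal(unname(back), unname(orig), tolerance = 1e-12)
})

test_that("stratified split preserves class fractions and validates", {
  ds <- generate_synthetic(synthetic_config(n_samples = 699, seed = 4))
  sp <- split_train_test(ds, 0.7, seed = 10)
  n_tr <- nrow(sp$train$X)
  expect_true(abs(n_tr - round(0.7 * 699)) <= 1)
  expect_equal(n_tr + nrow(sp$test$X), 699)
  # class fraction preserved within one sample per class
  for (cls in 0:1) {
    expect_true(abs(sum(sp$train$y == cls) - 0.7 * sum(ds$y == cls)) <= 1)
  }
  # same seed gives an identical split
  sp2 <- split_train_test(ds, 0.7, seed = 10)
  expect_identical(sp$train$X, sp2$train$X)
  # degenerate fraction that empties a class on one side errors
  small <- subset_dataset(ds, c(which(ds$y == 1)[1:2], which(ds$y == 0)[1:8]))
  expect_error(split_train_test(small, 0.999), "absent")
})

test_that("k-fold indices partition the sample exactly once each", {
  folds <- kfold_indices(100, k = 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(lapply(folds, `[[`, "validate")) == 10))
  # 23 samples over 10 folds: sizes in {2, 3} summing to 23
  f23 <- kfold_indices(23, k = 10, seed = 2)
  sizes <- lengths(lapply(f23, `[[`, "validate"))
  expect_true(all(sizes %in% 2:3))
  expect_equal(sum(sizes), 23)
  # union of validation folds is everything, pairwise disjoint
  all_idx <- sort(unlist(lapply(f23, `[[`, "validate")))
  expect_identical(all_idx, 1:23)
  for (f in f23) {
    expect_length(intersect(f$fit, f$validate), 0)
    expect_identical(sort(c(f$fit, f$validate)), 1:23)
  }
  expect_error(kfold_indices(5, k = 10), "exceed")
})

test_that("synthetic generator honors imbalance, signal and missingness", {
  ds <- generate_synthetic(synthetic_config(n_samples = 699,
                                            positive_fraction = 241 / 699,
                                            seed = 6))
  expect_equal(sum(ds$y), 241)
  expect_equal(nrow(ds$X), 699)
  expect_equal(ds$provenance, "synthetic")

  # no signal (delta = 0): a trained linear rule cannot beat the prior by much
  ds0 <- generate_synthetic(synthetic_config(n_samples = 400, delta = 0,
                                             seed = 7))
  prior <- max(mean(ds0$y), 1 - mean(ds0$y))
  fit <- glm(y ~ ., data = data.frame(y = ds0$y, ds0$X),
             family = binomial())
  acc <- mean((predict(fit, type = "response") >= 0.5) == ds0$y)
  expect_lt(acc, prior + 0.08)

  # ordinal mode stays on the 1..10 grid
  dso <- generate_synthetic(synthetic_config(n_samples = 100, ordinal = TRUE,
                                             seed = 8))
  expect_true(all(dso$X %in% 1:10))

  # missing-value injection blanks exactly the requested count
  dsm <- generate_synthetic(synthetic_config(n_samples = 100, ordinal = TRUE,
                                             missing_rate = 0.13, seed = 9))
  expect_equal(sum(is.na(dsm$raw$data$bare_nuclei)), 13)
  dsn <- generate_synthetic(synthetic_config(n_samples = 100, ordinal = TRUE,
                                             seed = 9))
  expect_null(dsn$raw)

  # seeded determinism
  a <- generate_synthetic(synthetic_config(n_samples = 50, seed = 11))
  b <- generate_synthetic(synthetic_config(n_samples = 50, seed = 11))
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
})

test_that("dataset CSV export writes features, labels and a JSON sidecar", {
  ds <- generate_synthetic(synthetic_config(n_samples = 20, seed = 12))
  nm <- minmax_fit_apply(ds)
  f <- tempfile(fileext = ".csv")
  save_dataset_csv(nm$train, f, ranges = nm$ranges)
  back <- read.csv(f)
  expect_equal(nrow(back), 20)
  expect_equal(back$class, ds$y)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$label_map$malignant, 1)
  expect_equal(side$ranges$min, nm$ranges$min)
  unlink(c(f, paste0(f, ".json")))
})
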