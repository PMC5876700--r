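test_that("stratified folds partition trials with near-equal class counts", {
  y <- rep(c(1, -1), each = 15)
  f <- stratified_folds(y, 5, seed = 3)
  expect_length(f, 30)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 6))
  expect_true(all(table(f, y) == 3))
  expect_identical(f, stratified_folds(y, 5, seed = 3))
  expect_false(identical(f, stratified_folds(y, 5, seed = 4)))
  # unbalanced classes: per-class counts differ by at most one across folds
  y2 <- rep(c(1, -1), c(17, 13))
  f2 <- stratified_folds(y2, 5, seed = 1)
  expect_true(all(abs(apply(table(f2, y2), 2, function(ct) diff(range(ct)))) <= 1))
  expect_error(stratified_folds(y, 1, seed = 1), class = "ssvephase_validation_error")
  expect_error(stratified_folds(y, 16, seed = 1), class = "ssvephase_validation_error")
})

test_that("noiseless antipodal data is decoded perfectly in every fold", {
  ds <- clean_dataset(12, per_class = 15)
  r <- suppressWarnings(evaluate_combination(ds, "C14", seed = 1))
  expect_length(r$per_fold_accuracy, 5)
  expect_equal(r$per_fold_accuracy, rep(1, 5))
  expect_equal(sort(r$predictions$trial), 1:30)
})

test_that("label-permuted data scores inside the chance band", {
  ds <- noisy_dataset(frequency = 12, snr = 10, seed = 51)
  set.seed(99)
  perm <- sample(30)
  shuffled <- ds
  for (i in 1:30) shuffled$trials[[i]]$label <- ds$trials[[perm[i]]]$label
  r <- suppressWarnings(evaluate_combination(shuffled, "C14", seed = 2))
  correct <- sum(r$predictions$predicted == r$predictions$truth)
  band <- qbinom(c(0.005, 0.995), 30, 0.5)
  expect_gte(correct, band[1])
  expect_lte(correct, band[2])
})

test_that("fitted artifacts never read held-out trials (poisoning check)", {
  ds <- noisy_dataset(frequency = 12, snr = 5, seed = 61)
  y <- dataset_labels(ds)$class_sign
  fold_id <- stratified_folds(y, 5, seed = 7)
  tr <- which(fold_id != 1)
  poisoned <- ds
  for (i in which(fold_id == 1)) poisoned$trials[[i]]$data[] <- NaN
  fm_clean <- fit_feature_model(ssvep_dataset(ds$trials[tr]), "C15")
  fm_pois <- fit_feature_model(ssvep_dataset(poisoned$trials[tr]), "C15")
  expect_identical(fm_clean$templates$templates, fm_pois$templates$templates)
  expect_identical(lapply(fm_clean$references$channels, `[[`, "references"),
                   lapply(fm_pois$references$channels, `[[`, "references"))
})

test_that("the sweep pairs all 15 combinations on shared folds", {
  ds <- noisy_dataset(frequency = 12, snr = 10, per_class = 5, seed = 71)
  sw <- suppressWarnings(sweep_combinations(ds, seed = 3, folds = 5,
                                            inner_folds = 4))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 15 * 5)
  expect_equal(unique(sw$combination), paste0("C", 1:15))
  results <- attr(sw, "results")
  fold_of_trial <- lapply(results, function(r) {
    p <- r$predictions; p$fold[order(p$trial)]
  })
  for (i in 2:15) expect_identical(fold_of_trial[[i]], fold_of_trial[[1]])
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
})

test_that("mean fold accuracy equals pooled accuracy for equal-size folds", {
  ds <- noisy_dataset(frequency = 15, snr = 10, seed = 81)
  r <- suppressWarnings(evaluate_combination(ds, "C2", seed = 5))
  pooled <- mean(r$predictions$predicted == r$predictions$truth)
  expect_equal(mean(r$per_fold_accuracy), pooled, tolerance = 1e-12)
})

test_that("noiseless four-target data is decoded perfectly by arbitration", {
  cfg <- synthetic_config(snr = Inf, seed = 5)
  ds <- generate_dataset(cfg)
  r <- suppressWarnings(decode_four_class(ds, "C14", seed = 1))
  expect_equal(r$per_fold_accuracy, rep(1, 5))
  expect_equal(r$frequency, "joint")
})

test_that("four-class decoding of pure noise stays inside the chance band", {
  cfg <- synthetic_config(snr = 0, seed = 15)
  ds <- generate_dataset(cfg)
  r <- suppressWarnings(decode_four_class(ds, "C14", seed = 2))
  correct <- sum(r$predictions$correct)
  band <- qbinom(c(0.005, 0.995), 60, 0.25)
  expect_gte(correct, band[1])
  expect_lte(correct, band[2])
  expect_error(decode_four_class(split_by_frequency(ds, 12), "C14"),
               class = "ssvephase_validation_error")
})

test_that("the exact Wilcoxon p-value matches full sign enumeration", {
  # oracle: enumerate all 2^n sign assignments of the rank sum
  enum_p <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_le <- mean(w_all <= w_obs + 1e-9)
    p_ge <- mean(w_all >= w_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  a <- c(0.9, 0.85, 0.8, 0.95, 0.7)
  b <- c(0.8, 0.80, 0.7, 0.90, 0.6)   # 5 positive, distinct differences
  res <- paired_wilcoxon_bonferroni(a, b, comparisons = 3)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$p_value, enum_p(a - b))
  expect_equal(res$threshold, 0.05 / 3)
  expect_false(res$significant)    # 0.0625 > 0.0167
  set.seed(23)
  for (i in 1:5) {
    d <- round(rnorm(8), 2)
    d <- d[d != 0]
    res_i <- paired_wilcoxon_bonferroni(d, numeric(length(d)))
    expect_equal(res_i$p_value, enum_p(d), tolerance = 1e-12)
  }
})

test_that("the signed-rank test agrees with the classical implementation", {
  set.seed(31)
  a <- runif(10, 0.6, 1)
  b <- a - runif(10, -0.05, 0.15)
  res <- paired_wilcoxon_bonferroni(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_warning(r0 <- paired_wilcoxon_bonferroni(a, a), "zero")
  expect_equal(r0$p_value, 1)
  expect_error(paired_wilcoxon_bonferroni(a, b[1:5]),
               class = "ssvephase_validation_error")
})

test_that("large-sample signed-rank p-values use the tie-corrected normal form", {
  set.seed(41)
  d <- round(rnorm(30, 0.05, 0.1), 2)   # ties likely, n > 25
  d <- d[d != 0]
  res <- paired_wilcoxon_bonferroni(d, numeric(length(d)))
  expect_equal(res$method, "normal")
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})
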