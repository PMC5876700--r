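# Cross-validated decoding accuracy per feature combination, the exhaustive
# combination sweep, the dual-classifier frequency-and-phase decoder, and the
# paired Wilcoxon / Bonferroni comparison.

#' Stratified fold assignment
#'
#' Per class, the trial indices are shuffled with a seeded RNG and dealt
#' round-robin into `k` folds, so folds are disjoint, cover all trials, and
#' per-class counts differ by at most one across folds.
#'
#' @param labels class label per trial (any atomic type).
#' @param k number of folds (2 <= k <= smallest class size).
#' @param seed integer seed fixing the assignment.
#' @return integer vector of fold ids in 1..k, one per trial.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  n <- length(labels)
  class_sizes <- table(labels)
  if (k < 2) stop_validation("k must be at least 2")
  if (k > min(class_sizes)) {
    stop_validation("k (", k, ") exceeds the smallest class size (",
                    min(class_sizes), ")")
  }
  with_seed(seed, {
    fold <- integer(n)
    for (cl in names(class_sizes)) {
      idx <- which(as.character(labels) == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated binary phase-decoding accuracy for one combination
#'
#' Runs a stratified outer k-fold (default 5) on a single-frequency dataset.
#' Per fold, the feature artifacts (templates, reference segments), the
#' feature scaler and the LS-SVM — with inner stratified 10-fold Nelder-Mead
#' hyperparameter tuning — are fitted on the training trials only; the held
#' out trials are then featurized and classified.
#'
#' @param dataset a balanced single-frequency [ssvep_dataset()].
#' @param combination feature-set combination (id, subset or `+` syntax).
#' @param seed integer seed fixing outer folds and inner tuning folds.
#' @param folds outer fold count.
#' @param inner_folds inner tuning fold count (clamped to class sizes).
#' @param fold_id optional precomputed outer fold assignment (used by
#'   [sweep_combinations()] so all combinations share folds).
#' @return an object of class `cv_result`: `per_fold_accuracy`, `predictions`
#'   (data frame: trial, fold, truth, predicted, confidence), `combination`,
#'   `frequency`, `subject`.
#' @export
evaluate_combination <- function(dataset, combination, seed = 1, folds = 5,
                                 inner_folds = 10, fold_id = NULL) {
  sets <- resolve_combination(combination)
  if (length(dataset$frequencies) != 1L) {
    stop_validation("evaluate_combination needs a single-frequency dataset; use ",
                    "split_by_frequency() or decode_four_class()")
  }
  labs <- dataset_labels(dataset)
  y <- labs$class_sign
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed)
  k <- max(fold_id)
  acc <- numeric(k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    train_set <- ssvep_dataset(dataset$trials[tr], metadata = dataset$metadata)
    fm <- fit_feature_model(train_set, sets)
    xtr <- featurize_dataset(train_set, fm)
    ytr <- y[tr]
    tuned <- tune_hyperparameters(xtr, ytr, folds = inner_folds, seed = seed + f)
    model <- suppressWarnings(lssvm_train(xtr, ytr, tuned$gamma, tuned$sigma2))
    test_set <- ssvep_dataset(dataset$trials[te], metadata = dataset$metadata)
    xte <- featurize_dataset(test_set, fm)
    pr <- lssvm_predict(model, xte)
    acc[f] <- mean(pr$labels == y[te])
    preds[[f]] <- data.frame(trial = te, fold = f, truth = y[te],
                             predicted = pr$labels, confidence = pr$confidence)
  }
  structure(
    list(per_fold_accuracy = acc,
         predictions = do.call(rbind, preds),
         combination = paste(sets, collapse = "+"),
         frequency = dataset$frequencies,
         subject = paste(unique(labs$subject), collapse = ",")),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s @ %s Hz | subject %s | mean acc %.3f (folds: %s)\n",
              x$combination, paste(x$frequency, collapse = "+"), x$subject,
              mean(x$per_fold_accuracy),
              paste(sprintf("%.2f", x$per_fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Evaluate all 15 feature-set combinations
#'
#' Runs [evaluate_combination()] for C1..C15 with a single shared outer fold
#' assignment, so accuracies are paired across combinations.
#'
#' @inheritParams evaluate_combination
#' @return a data frame of class `sweep_result`: one row per (combination,
#'   fold) with the fold accuracy; attribute `results` holds the full
#'   `cv_result` objects.
#' @export
sweep_combinations <- function(dataset, seed = 1, folds = 5, inner_folds = 10) {
  labs <- dataset_labels(dataset)
  fold_id <- stratified_folds(labs$class_sign, folds, seed)
  combos <- enumerate_combinations()
  results <- lapply(names(combos), function(id) {
    evaluate_combination(dataset, combos[[id]], seed = seed,
                         inner_folds = inner_folds, fold_id = fold_id)
  })
  names(results) <- names(combos)
  tab <- do.call(rbind, lapply(names(combos), function(id) {
    r <- results[[id]]
    data.frame(combination = id, fold = seq_along(r$per_fold_accuracy),
               accuracy = r$per_fold_accuracy, frequency = r$frequency,
               subject = r$subject)
  }))
  structure(tab, results = results, class = c("sweep_result", "data.frame"))
}

#' Boxplot of a combination sweep
#'
#' One box per combination C1..C15 summarising fold (or subject) accuracies:
#' median line, first-to-third quartile box, whiskers at 1.5 IQR, outliers
#' as points.
#'
#' @param x a `sweep_result` (or any data frame with `combination` and
#'   `accuracy` columns).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.sweep_result <- function(x, ...) {
  x$combination <- factor(x$combination, levels = paste0("C", 1:15))
  graphics::boxplot(accuracy ~ combination, data = x, pch = 3,
                    xlab = "feature combination", ylab = "accuracy",
                    ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Four-class frequency-and-phase decoding with dual-classifier arbitration
#'
#' Stratified k-fold CV over all four (frequency, phase) cells. Per fold, one
#' binary phase pipeline (feature artifacts + tuned LS-SVM) is fitted per
#' base frequency on that frequency's training trials. Each held-out trial is
#' featurized twice — once under each frequency assumption — and classified
#' by the corresponding model; the classifier with the higher posterior
#' confidence wins and contributes its frequency plus predicted phase class
#' as the 4-class prediction. Exact confidence ties (a measure-zero event)
#' break deterministically to the lower frequency with a warning.
#'
#' @param dataset an [ssvep_dataset()] containing both frequencies and both
#'   phases.
#' @param combination feature-set combination used by both binary pipelines.
#' @param seed integer seed for folds and tuning.
#' @param folds outer fold count.
#' @param inner_folds inner tuning fold count.
#' @return an object of class `cv_result` with 4-class per-fold accuracies;
#'   `predictions` records the true and predicted (frequency, phase) pairs
#'   and both classifiers' confidences.
#' @export
decode_four_class <- function(dataset, combination, seed = 1, folds = 5,
                              inner_folds = 10) {
  sets <- resolve_combination(combination)
  labs <- dataset_labels(dataset)
  freqs <- sort(dataset$frequencies)
  if (length(freqs) != 2L) {
    stop_validation("decode_four_class needs exactly 2 base frequencies, got ",
                    length(freqs))
  }
  cell <- interaction(labs$frequency, labs$phase, drop = TRUE)
  if (nlevels(cell) != 4L) {
    stop_validation("all four (frequency, phase) cells must be present; found ",
                    nlevels(cell))
  }
  fold_id <- stratified_folds(cell, folds, seed)
  k <- max(fold_id)
  acc <- numeric(k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    pipelines <- lapply(freqs, function(fq) {
      sub <- tr[labs$frequency[tr] == fq]
      train_set <- ssvep_dataset(dataset$trials[sub], metadata = dataset$metadata)
      fm <- fit_feature_model(train_set, sets)
      xtr <- featurize_dataset(train_set, fm)
      tuned <- tune_hyperparameters(xtr, labs$class_sign[sub],
                                    folds = inner_folds, seed = seed + f)
      model <- suppressWarnings(
        lssvm_train(xtr, labs$class_sign[sub], tuned$gamma, tuned$sigma2))
      list(feature_model = fm, model = model)
    })
    names(pipelines) <- as.character(freqs)
    test_set <- ssvep_dataset(dataset$trials[te], metadata = dataset$metadata)
    per_freq <- lapply(pipelines, function(p) {
      x <- featurize_dataset(test_set, p$feature_model)
      lssvm_predict(p$model, x)
    })
    conf <- vapply(per_freq, function(p) p$confidence, numeric(length(te)))
    conf <- matrix(conf, nrow = length(te))
    tie <- abs(conf[, 1] - conf[, 2]) == 0
    if (any(tie)) {
      warning(sum(tie), " exact confidence tie(s); choosing the lower frequency",
              call. = FALSE)
    }
    winner <- ifelse(conf[, 2] > conf[, 1], 2L, 1L)
    pred_freq <- freqs[winner]
    pred_sign <- vapply(seq_along(te), function(i) {
      per_freq[[winner[i]]]$labels[i]
    }, numeric(1))
    correct <- pred_freq == labs$frequency[te] & pred_sign == labs$class_sign[te]
    acc[f] <- mean(correct)
    preds[[f]] <- data.frame(
      trial = te, fold = f,
      true_frequency = labs$frequency[te], true_sign = labs$class_sign[te],
      pred_frequency = pred_freq, pred_sign = pred_sign,
      confidence_low = conf[, 1], confidence_high = conf[, 2],
      correct = correct)
  }
  structure(
    list(per_fold_accuracy = acc, predictions = do.call(rbind, preds),
         combination = paste(sets, collapse = "+"),
         frequency = "joint",
         subject = paste(unique(labs$subject), collapse = ",")),
    class = "cv_result"
  )
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-sided signed-rank test on the paired differences `a - b`. Zero
#' differences are dropped (classical convention). With at most 25 non-zero
#' differences the null distribution of the positive-rank sum is computed
#' exactly by enumerating all sign assignments (via a convolution over the
#' tied-rank values, so ties are handled exactly); beyond that a normal
#' approximation with tie correction is used. Significance is declared when
#' `p < 0.05 / comparisons`.
#'
#' @param accuracies_a,accuracies_b equal-length paired per-subject accuracy
#'   vectors.
#' @param comparisons number of comparisons in the family (the Bonferroni
#'   divisor).
#' @return list with `p_value`, `statistic` (positive-rank sum W),
#'   `significant`, `threshold`, `n_nonzero` and `method` ("exact" or
#'   "normal").
#' @export
paired_wilcoxon_bonferroni <- function(accuracies_a, accuracies_b,
                                       comparisons = 3) {
  if (length(accuracies_a) != length(accuracies_b)) {
    stop_validation("paired vectors must have equal length")
  }
  threshold <- 0.05 / comparisons
  d <- accuracies_a - accuracies_b
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; returning p = 1", call. = FALSE)
    return(list(p_value = 1, statistic = NA_real_, significant = FALSE,
                threshold = threshold, n_nonzero = 0L, method = "degenerate"))
  }
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  n <- length(nz)
  if (n <= 25L) {
    # Exact null: distribution of sum of a random subset of the (tied) ranks.
    # Doubling makes average ranks integral so a convolution table applies.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- c(1, numeric(total))           # dist[s + 1] = #assignments with sum s
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(total + 1 - ri)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p_value = p, statistic = w, significant = p < threshold,
       threshold = threshold, n_nonzero = n, method = method)
}

#' Per-subject accuracy table for a multi-subject dataset
#'
#' Convenience driver: runs [evaluate_combination()] (or
#' [decode_four_class()] when `four_class = TRUE`) independently for each
#' subject and returns one mean accuracy per subject, the unit over which
#' group-level boxplots and paired tests operate.
#'
#' @param dataset an [ssvep_dataset()] with one or more subjects.
#' @param combination feature-set combination.
#' @param seed integer seed; each subject s uses `seed + s` for folds/tuning.
#' @param frequency base frequency to evaluate (ignored for 4-class).
#' @param four_class run the joint frequency-and-phase decoder instead.
#' @param folds,inner_folds CV fold counts.
#' @return data frame with columns `subject` and `accuracy`.
#' @export
per_subject_accuracy <- function(dataset, combination, seed = 1,
                                 frequency = NULL, four_class = FALSE,
                                 folds = 5, inner_folds = 10) {
  subjects <- unique(dataset_subjects(dataset))
  rows <- lapply(seq_along(subjects), function(i) {
    ds <- split_by_subject(dataset, subjects[i])
    r <- if (four_class) {
      decode_four_class(ds, combination, seed = seed + i, folds = folds,
                        inner_folds = inner_folds)
    } else {
      dsf <- if (is.null(frequency)) ds else split_by_frequency(ds, frequency)
      evaluate_combination(dsf, combination, seed = seed + i, folds = folds,
                           inner_folds = inner_folds)
    }
    data.frame(subject = subjects[i], accuracy = mean(r$per_fold_accuracy))
  })
  do.call(rbind, rows)
}
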