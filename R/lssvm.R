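# Least-squares SVM with RBF kernel: closed-form training via one linear
# system, Platt-style posterior calibration, and Nelder-Mead hyperparameter
# tuning under stratified k-fold cross-validation.

rbf_kernel_from_dist2 <- function(d2, sigma2) exp(-d2 / sigma2)

# Squared Euclidean distances between the rows of a and b.
pairwise_dist2 <- function(a, b = a) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# Per-feature standardisation learned on training data. Zero-variance
# columns are dropped with a warning (they carry no information and would
# corrupt the shared kernel bandwidth).
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance feature column(s)",
            call. = FALSE)
  }
  list(center = unname(mu[keep]), scale = unname(sdv[keep]),
       keep = which(keep), n_in = ncol(x))
}

apply_scaler <- function(scaler, x) {
  x <- x[, scaler$keep, drop = FALSE]
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

# Platt-style sigmoid calibration (Lin, Lin & Weng's robust Newton variant):
# fit (A, B) so that P(y = +1 | f) = 1 / (1 + exp(A f + B)), with smoothed
# targets to avoid degenerate fits on separable data. A is clamped to <= 0 so
# the posterior is non-decreasing in the latent.
fit_platt <- function(latents, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  t_i <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  obj <- function(a, b) {
    z <- a * latents + b
    # stable cross-entropy: t*z + log(1 + exp(-z))
    sum(ifelse(z >= 0, t_i * z + log1p(exp(-z)), (t_i - 1) * z + log1p(exp(z))))
  }
  f_old <- obj(a, b)
  for (iter in 1:100) {
    z <- a * latents + b
    p <- 1 / (1 + exp(z))          # P(y=+1)
    d1 <- t_i - p                  # gradient pieces
    g_a <- sum(d1 * latents)
    g_b <- sum(d1)
    w <- p * (1 - p)
    h_aa <- sum(w * latents^2) + 1e-12
    h_ab <- sum(w * latents)
    h_bb <- sum(w) + 1e-12
    det <- h_aa * h_bb - h_ab^2
    if (abs(det) < 1e-20) break
    da <- -(h_bb * g_a - h_ab * g_b) / det
    db <- -(h_aa * g_b - h_ab * g_a) / det
    step <- 1
    repeat {
      f_new <- obj(a + step * da, b + step * db)
      if (f_new <= f_old + 1e-4 * step * (g_a * da + g_b * db) || step < 1e-10) break
      step <- step / 2
    }
    a <- a + step * da
    b <- b + step * db
    if (abs(f_old - f_new) < 1e-10) { f_old <- f_new; break }
    f_old <- f_new
  }
  if (a > 0) a <- 0  # enforce monotone (non-decreasing) posterior
  list(A = a, B = b)
}

#' Train a least-squares SVM
#'
#' Standardises the features (training statistics), then solves the LS-SVM
#' dual system
#' \deqn{\begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ 1 \end{bmatrix}}
#' with \eqn{\Omega_{ij} = y_i y_j K(x_i, x_j)} and the RBF kernel
#' \eqn{K(x, z) = \exp(-\|x - z\|^2 / \sigma^2)}. The latent output is
#' \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b}; a Platt-style sigmoid
#' fitted on the training latents maps it to a posterior probability.
#'
#' @param features numeric matrix, examples x dimensions.
#' @param labels vector of +/-1 class labels, at least one example per class.
#' @param gamma regularisation strength (> 0); larger means less
#'   regularisation.
#' @param sigma2 RBF kernel bandwidth (squared length scale, > 0).
#' @return an object of class `lssvm_model`.
#' @export
lssvm_train <- function(features, labels, gamma = 1, sigma2 = 1) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) {
    stop_validation("labels must be +/-1")
  }
  if (length(unique(labels)) < 2L) {
    stop_validation("training needs at least one example of each class")
  }
  if (nrow(features) != length(labels)) {
    stop_validation("features and labels disagree on the number of examples")
  }
  if (!all(is.finite(features))) stop_validation("features contain non-finite values")
  if (!(gamma > 0) || !(sigma2 > 0)) {
    stop_validation("gamma and sigma2 must be positive")
  }
  scaler <- fit_scaler(features)
  if (length(scaler$keep) == 0L) {
    stop_validation("all feature columns have zero variance")
  }
  x <- apply_scaler(scaler, features)
  m <- nrow(x)
  K <- rbf_kernel_from_dist2(pairwise_dist2(x), sigma2)
  Omega <- tcrossprod(labels) * K
  A <- rbind(c(0, labels), cbind(labels, Omega + diag(m) / gamma))
  sol <- tryCatch(solve(A, c(0, rep(1, m))),
                  error = function(e) {
                    stop("LS-SVM system is numerically singular (",
                         conditionMessage(e),
                         "); consider lowering gamma", call. = FALSE)
                  })
  b <- unname(sol[1])
  alpha <- unname(sol[-1])
  latents <- as.numeric(K %*% (alpha * labels) + b)
  model <- structure(
    list(support_coefficients = alpha, bias = b, gamma = gamma, sigma2 = sigma2,
         training_inputs = x, training_labels = labels, scaler = scaler,
         calibration = fit_platt(latents, labels)),
    class = "lssvm_model"
  )
  model
}

#' Predict with a trained LS-SVM
#'
#' @param model an [lssvm_train()] result.
#' @param features numeric matrix with the training feature dimensionality.
#' @return list with `labels` (+/-1; a latent of exactly 0 maps to +1),
#'   `latents`, `posteriors` (calibrated P(class +1)) and `confidence`
#'   (`max(posterior, 1 - posterior)`).
#' @export
lssvm_predict <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$scaler$n_in) {
    stop_validation("feature dimension (", ncol(features),
                    ") does not match the training dimension (",
                    model$scaler$n_in, ")")
  }
  x <- apply_scaler(model$scaler, features)
  K <- rbf_kernel_from_dist2(pairwise_dist2(x, model$training_inputs),
                             model$sigma2)
  latents <- as.numeric(K %*% (model$support_coefficients * model$training_labels) +
                          model$bias)
  post <- 1 / (1 + exp(model$calibration$A * latents + model$calibration$B))
  post <- pmin(pmax(post, 1e-12), 1 - 1e-12)
  list(labels = ifelse(latents >= 0, 1, -1),
       latents = latents,
       posteriors = post,
       confidence = pmax(post, 1 - post))
}

#' Tune LS-SVM hyperparameters by simplex search under stratified CV
#'
#' Minimises the mean stratified k-fold cross-validated misclassification
#' rate over `(log10 gamma, log10 sigma2)` with Nelder-Mead, starting from
#' `gamma = 1` and `sigma2 =` the median pairwise squared distance of the
#' standardised training features. Both parameters are clipped to
#' `[1e-3, 1e6]`. Among parameter settings of equal CV error the search is
#' nudged (by a negligible penalty) toward smaller `gamma`, then smaller
#' `sigma2`, making model selection deterministic. The fold assignment is
#' fixed by `seed`.
#'
#' @param features numeric matrix, examples x dimensions.
#' @param labels +/-1 vector.
#' @param folds number of CV folds (clamped to the smallest class size).
#' @param seed integer seed fixing the fold assignment.
#' @param maxit Nelder-Mead iteration cap.
#' @return list with `gamma`, `sigma2` and the achieved `cv_error`.
#' @export
tune_hyperparameters <- function(features, labels, folds = 10, seed = 1,
                                 maxit = 200) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  scaler <- fit_scaler(features)
  if (length(scaler$keep) == 0L) {
    stop_validation("all feature columns have zero variance")
  }
  x <- apply_scaler(scaler, features)
  m <- nrow(x)
  d2 <- pairwise_dist2(x)
  class_sizes <- table(labels)
  k <- min(folds, min(class_sizes))
  fold_id <- stratified_folds(labels, k, seed)
  off <- d2[upper.tri(d2)]
  s2_init <- stats::median(off[off > 0])
  if (!is.finite(s2_init) || s2_init <= 0) s2_init <- 1
  box <- c(1e-3, 1e6)
  clip <- function(v) pmin(pmax(v, log10(box[1])), log10(box[2]))

  cv_error <- function(th) {
    th <- clip(th)
    gamma <- 10^th[1]
    sigma2 <- 10^th[2]
    K <- rbf_kernel_from_dist2(d2, sigma2)
    errs <- vapply(seq_len(k), function(f) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      ytr <- labels[tr]
      Omega <- tcrossprod(ytr) * K[tr, tr, drop = FALSE]
      A <- rbind(c(0, ytr), cbind(ytr, Omega + diag(length(tr)) / gamma))
      sol <- tryCatch(solve(A, c(0, rep(1, length(tr)))),
                      error = function(e) NULL)
      if (is.null(sol)) return(1)
      lat <- as.numeric(K[te, tr, drop = FALSE] %*% (sol[-1] * ytr) + sol[1])
      mean(ifelse(lat >= 0, 1, -1) != labels[te])
    }, numeric(1))
    # vanishing tie-break penalty: prefer smaller gamma, then smaller sigma2
    mean(errs) + 1e-9 * th[1] + 1e-12 * th[2]
  }

  opt <- stats::optim(c(0, log10(s2_init)), cv_error, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  th <- clip(opt$par)
  list(gamma = 10^th[1], sigma2 = 10^th[2], cv_error = opt$value)
}
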