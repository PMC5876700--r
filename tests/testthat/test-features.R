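t256 <- (0:255) / 512

test_that("svd_align recovers the shared waveform of a rank-1 epoch", {
  w <- cos(2 * pi * 12 * t256 + 0.4)
  mk <- function(m) ssvep_trial(m, 512, target_label(12, 0),
                                channel_names = c("Oz", "O1", "O2"))
  same <- svd_align(mk(rbind(w, w, w)))
  expect_equal(abs(cor(same$aligned, w)), 1, tolerance = 1e-12)
  gains <- svd_align(mk(outer(c(1, 2, 3), w)))
  expect_equal(abs(cor(gains$aligned, w)), 1, tolerance = 1e-12)
  expect_gte(cor(gains$aligned, colMeans(gains$source$data)), 0)
  expect_error(svd_align(mk(matrix(0, 3, 256))),
               class = "ssvephase_degenerate_error")
  expect_error(svd_align(clean_trial()[["data"]][1:2, ] |>
                           ssvep_trial(512, target_label(12, 0))),
               class = "ssvephase_validation_error")
})

test_that("svd_align matches a power-iteration oracle under noise", {
  set.seed(4)
  w <- cos(2 * pi * 12 * t256)
  X <- outer(c(1, 0.8, 0.9), w) + matrix(rnorm(3 * 256, sd = 0.01 * sqrt(sum(w^2))),
                                         3, 256)
  tr <- ssvep_trial(X, 512, target_label(12, 0),
                    channel_names = c("Oz", "O1", "O2"))
  al <- svd_align(tr)$aligned
  expect_gte(cor(al, w), 0.99)
  # oracle: dominant eigenvector of X'X by power iteration
  v <- rnorm(256)
  for (i in 1:200) { v <- crossprod(X, X %*% v); v <- v / sqrt(sum(v^2)) }
  expect_gte(abs(cor(al, as.numeric(v))), 1 - 1e-8)
})

test_that("the ML phase estimator is exact for integer-period cosines", {
  r0 <- cos(2 * pi * 12 * t256)
  expect_angle_equal(estimate_phase_ml(r0, 12, 512), 0, tol = 1e-9)
  expect_angle_equal(estimate_phase_ml(-r0, 12, 512), pi, tol = 1e-9)
  expect_angle_equal(estimate_phase_ml(cos(2 * pi * 12 * t256 + pi / 3), 12, 512),
                     pi / 3, tol = 1e-6)
  # closed-form continuous-time oracle: projections of cos(2pi f t + phi)
  # onto the carrier pair over whole periods are (n/2)cos(phi), -(n/2)sin(phi)
  phi <- 2 * pi / 7
  num <- -256 / 2 * sin(phi)   # integral of r(t) sin(2 pi f t)
  den <- 256 / 2 * cos(phi)    # integral of r(t) cos(2 pi f t)
  expect_angle_equal(atan2(-num, den),
                     estimate_phase_ml(cos(2 * pi * 12 * t256 + phi), 12, 512),
                     tol = 1e-9)
})

test_that("the ML phase estimator is amplitude-invariant and antipode-covariant", {
  set.seed(9)
  for (i in 1:20) {
    phi <- runif(1, -pi, pi)
    f <- sample(c(12, 15), 1)
    r <- cos(2 * pi * f * t256 + phi) + rnorm(256, sd = 0.3)
    p1 <- estimate_phase_ml(r, f, 512)
    expect_angle_equal(estimate_phase_ml(3.7 * r, f, 512), p1, tol = 1e-12)
    expect_angle_equal(estimate_phase_ml(-r, f, 512), p1 + pi, tol = 1e-9)
    expect_true(p1 > -pi && p1 <= pi)
  }
  expect_error(estimate_phase_ml(numeric(256) + 0, 12, 512),
               class = "ssvephase_degenerate_error")
  expect_error(estimate_phase_ml(cos(t256), 300, 512),
               class = "ssvephase_validation_error")
  expect_error(estimate_phase_ml(cos(2 * pi * 12 * t256)[1:20], 12, 512),
               class = "ssvephase_validation_error")
})

test_that("class templates recover the class waveform", {
  ds <- clean_dataset(12, per_class = 5)
  tpl <- build_class_templates(ds)
  w <- cos(2 * pi * 12 * t256)
  expect_equal(cor(tpl$templates$Oz$pos, w), 1, tolerance = 1e-9)
  expect_equal(sum(tpl$templates$Oz$pos^2), 1, tolerance = 1e-12)
  # antipodal classes give antipodal templates
  expect_lte(cor(tpl$templates$Oz$pos, tpl$templates$Oz$neg), -0.99)
  expect_named(tpl$templates, c("Oz", "O1", "O2", "aligned"))
})

test_that("templates from noisy epochs match the normalized class mean oracle", {
  set.seed(12)
  w <- cos(2 * pi * 12 * t256 + 0.7)
  mk <- function(phase, noise_sd) {
    sgn <- if (phase == 0) 1 else -1
    x <- sgn * w + rnorm(256, sd = noise_sd)
    ssvep_trial(rbind(x, x + rnorm(256, sd = noise_sd), x + rnorm(256, sd = noise_sd)),
                512, target_label(12, phase), channel_names = c("Oz", "O1", "O2"))
  }
  sd0 <- 0.05 * sqrt(sum(w^2) / 256)
  trials <- c(lapply(1:15, function(i) mk(0, sd0)),
              lapply(1:15, function(i) mk(pi, sd0)))
  ds <- ssvep_dataset(trials)
  tpl <- build_class_templates(ds)
  expect_gte(cor(tpl$templates$Oz$pos, w), 0.99)
  # oracle: the normalized class mean approximates the dominant component
  class_mean <- colMeans(do.call(rbind, lapply(trials[1:15], function(t) t$data[1, ])))
  expect_gte(cor(tpl$templates$Oz$pos, class_mean), 0.999)
  # fewer than 2 trials per class is rejected
  expect_error(build_class_templates(ssvep_dataset(trials[c(1, 16)])),
               class = "ssvephase_validation_error")
})

test_that("template correlation features behave as self/anti correlations", {
  ds <- clean_dataset(12, per_class = 5)
  tpl <- build_class_templates(ds)
  f0 <- correlate_with_templates(ds$trials[[1]], tpl)   # a phase-0 trial
  expect_length(f0, 8)
  expect_equal(unname(f0["Oz.cor_pos"]), 1, tolerance = 1e-9)
  expect_lte(f0["Oz.cor_neg"], -0.99)
  fpi <- correlate_with_templates(ds$trials[[6]], tpl)  # a phase-pi trial
  expect_equal(unname(fpi["Oz.cor_neg"]), 1, tolerance = 1e-9)
  expect_true(all(abs(c(f0, fpi)) <= 1 + 1e-12))
})

test_that("template phase features reduce to the carrier ML phase for sinusoidal templates", {
  ds <- clean_dataset(12, per_class = 5)
  tpl <- build_class_templates(ds)
  probe <- clean_trial(12, pi / 2)
  f <- phase_vs_templates(probe, tpl)
  expect_length(f, 8)
  expect_angle_equal(f["Oz.phase_pos"], pi / 2, tol = 1e-3)
  expect_angle_equal(f["Oz.phase_neg"], -pi / 2, tol = 1e-3)
  # in-phase and antiphase probes
  f_same <- phase_vs_templates(ds$trials[[1]], tpl)
  expect_angle_equal(f_same["Oz.phase_pos"], 0, tol = 1e-6)
  expect_angle_equal(f_same["Oz.phase_neg"], pi, tol = 1e-6)
  # property: equals estimate_phase_ml against the same carrier
  set.seed(5)
  for (i in 1:10) {
    phi <- runif(1, -pi, pi)
    probe <- clean_trial(12, phi)
    f <- phase_vs_templates(probe, tpl)
    expect_angle_equal(f["Oz.phase_pos"],
                       estimate_phase_ml(probe$data[1, ], 12, 512), tol = 1e-3)
  }
})

test_that("one-period segment averaging yields 6 segments at 12 Hz, 7 at 15 Hz", {
  x12 <- average_period_segments(cos(2 * pi * 12 * t256), 12, 512)
  expect_length(x12, 42)
  expect_equal(attr(x12, "n_segments"), 6)
  x15 <- average_period_segments(cos(2 * pi * 15 * t256), 15, 512)
  expect_length(x15, 34)
  expect_equal(attr(x15, "n_segments"), 7)
  # an exactly x-periodic epoch averages to its first segment
  seg <- sin(1:42)
  per <- rep(seg, length.out = 256)
  expect_equal(as.numeric(average_period_segments(per, 12, 512)), seg,
               tolerance = 1e-12)
  expect_error(average_period_segments(seg[1:30], 12, 512),
               class = "ssvephase_validation_error")
})

test_that("reference selection matches a brute-force oracle on a noisy set", {
  ds <- noisy_dataset(frequency = 12, snr = 2, seed = 31)
  refs <- build_segment_references(ds)
  y <- dataset_labels(ds)$class_sign
  for (ci in 1:3) {
    S <- sapply(ds$trials, function(t)
      as.numeric(average_period_segments(t$data[ci, ], 12, 512)))
    expect_equal(refs$channels[[ci]]$index, brute_force_references(S, y))
  }
  expect_equal(refs$period_samples, 42)
  expect_length(refs$channels, 3)
  expect_true(all(vapply(refs$channels,
                         function(ch) ncol(ch$references) == 5L, logical(1))))
})

test_that("degenerate identical training segments tie-break to the lowest index", {
  ds <- clean_dataset(12, per_class = 3)
  w <- capture_warnings(refs <- build_segment_references(ds))
  expect_true(any(grepl("tie", w)))
  expect_equal(refs$channels$Oz$index[1], 1L)
})

test_that("reference correlation features are bounded and self-identifying", {
  ds <- noisy_dataset(frequency = 15, snr = 5, seed = 13)
  refs <- build_segment_references(ds)
  feats <- correlate_with_references(ds$trials[[1]], refs)
  expect_length(feats, 15)
  all_feats <- sapply(ds$trials, correlate_with_references, refs = refs)
  expect_true(all(all_feats >= -1 - 1e-12 & all_feats <= 1 + 1e-12))
  # a trial whose averaged segment IS a reference correlates at exactly 1
  sel <- refs$channels$Oz$index[1]
  f_sel <- correlate_with_references(ds$trials[[sel]], refs)
  expect_equal(unname(f_sel[1]), 1, tolerance = 1e-12)
})

test_that("feature vectors have the canonical dimensions per set and combination", {
  ds <- noisy_dataset(frequency = 12, snr = 5, seed = 17)
  fm <- fit_feature_model(ds, "C15")
  tr <- ds$trials[[1]]
  expect_length(extract_features(tr, fm, "I"), 4)
  expect_length(extract_features(tr, fm, "II"), 8)
  expect_length(extract_features(tr, fm, "III"), 8)
  expect_length(extract_features(tr, fm, "IV"), 15)
  expect_length(extract_features(tr, fm, "C14"), 31)
  f15 <- extract_features(tr, fm)
  expect_length(f15, 35)
  layout <- attr(f15, "layout")
  expect_equal(unname(table(layout$set)[c("I", "II", "III", "IV")]),
               c(4L, 8L, 8L, 15L), ignore_attr = TRUE)
  # order: I then II then III then IV; signals Oz, O1, O2 (, aligned)
  expect_equal(layout$set, rep(c("I", "II", "III", "IV"), c(4, 8, 8, 15)))
  expect_equal(layout$signal[1:4], c("Oz", "O1", "O2", "aligned"))
  # a model fitted without IV refuses IV extraction, naming the method
  fm2 <- fit_feature_model(ds, "C8")
  expect_error(extract_features(tr, fm2, "IV"), "IV")
})

test_that("all 15 combinations are enumerated in canonical order", {
  combos <- enumerate_combinations()
  expect_length(combos, 15)
  expect_named(combos, paste0("C", 1:15))
  expect_equal(combos$C14, c("II", "III", "IV"))
  expect_false("I" %in% combos$C14)
  expect_equal(combos$C15, c("I", "II", "III", "IV"))
  # the list is exactly the 2^4 - 1 non-empty subsets, no duplicates
  keys <- vapply(combos, paste, character(1), collapse = "+")
  expect_equal(length(unique(keys)), 15)
  expect_error(ssvephase:::resolve_combination("C99"), "C1..C15")
  expect_equal(ssvephase:::resolve_combination("II+III+IV"), c("II", "III", "IV"))
})
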