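# Feature extraction for phase-encoded SSVEP epochs.
#
# Four feature families are implemented:
#   I   maximum-likelihood phase of the epoch against the stimulation carrier
#   II  Pearson correlation with SVD-derived 0/pi phase-class templates
#   III ML phase of the epoch against each class template
#   IV  Pearson correlation of the epoch's averaged one-period segment with
#       five reference segments selected from the training set
# plus the SVD alignment that collapses the three occipital channels into a
# single "virtual" channel used as a fourth signal by families I-III.
#
# Feature-set dimensions per epoch: I -> 4, II -> 8, III -> 8, IV -> 15.

FEATURE_SETS <- c("I", "II", "III", "IV")

#' Align a 3-channel epoch into a single virtual channel by SVD
#'
#' Decomposes the channels-by-samples matrix `X = U S V'` and returns
#' `s1 * v1`, the dominant temporal component scaled by its singular value.
#' The sign ambiguity of the SVD is fixed so that the Pearson correlation of
#' the aligned signal with the channel-mean signal is non-negative (falling
#' back to the first channel, then to a positive leading coefficient, when
#' the mean is degenerate).
#'
#' @param trial an [ssvep_trial()] with exactly 3 channels (the occipital set).
#' @return an object of class `aligned_trial` with fields `aligned` (length-n
#'   numeric vector) and `source` (the input trial).
#' @export
svd_align <- function(trial) {
  if (nrow(trial$data) != 3L) {
    stop_validation("svd_align expects exactly 3 channels, got ", nrow(trial$data))
  }
  if (all(trial$data == 0)) {
    stop_degenerate("svd_align: all-zero (rank-0) epoch")
  }
  dec <- svd(trial$data, nu = 0, nv = 1)
  aligned <- dec$d[1] * dec$v[, 1]
  aligned <- fix_sign(aligned, colMeans(trial$data),
                      fallback = trial$data[1, ])
  structure(list(aligned = aligned, source = trial), class = "aligned_trial")
}

# Resolve an SVD sign ambiguity: flip `v` so cor(v, ref) >= 0. Degenerate
# references fall through to `fallback`, then to the sign of the largest
# coefficient.
fix_sign <- function(v, ref, fallback = NULL) {
  for (r in list(ref, fallback)) {
    if (is.null(r)) next
    if (stats::sd(r) > 0 && stats::sd(v) > 0) {
      rho <- stats::cor(v, r)
      if (!is.na(rho) && abs(rho) > 1e-12) {
        return(if (rho < 0) -v else v)
      }
    }
  }
  if (v[which.max(abs(v))] < 0) -v else v
}

#' Maximum-likelihood phase estimate of an epoch
#'
#' Estimates the phase of a sinusoidal carrier of known frequency embedded in
#' the epoch, as in phase-shift-keying demodulation: the quadrature
#' projections of the epoch onto the carrier pair give
#' `phi = atan2(-sum(r * sin(2 pi f t)), sum(r * cos(2 pi f t)))`,
#' wrapped to (-pi, pi]. For `r[t] = cos(2 pi f t + phi)` over an integer
#' number of carrier periods the estimate is exact. The quadrant-aware
#' arctangent keeps antipodal phases (0 vs pi) distinguishable, which a plain
#' arctangent of the ratio would collapse.
#'
#' @param epoch numeric vector (one channel, onset-locked).
#' @param f_c carrier (stimulation) frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return phase estimate in (-pi, pi], radians, relative to a cosine carrier.
#' @export
#' @examples
#' fs <- 512; t <- (0:255) / fs
#' estimate_phase_ml(cos(2 * pi * 12 * t + pi / 3), 12, fs)  # ~ pi/3
estimate_phase_ml <- function(epoch, f_c, fs) {
  if (!is.numeric(epoch) || length(epoch) < 2L) {
    stop_validation("epoch must be a numeric vector")
  }
  if (f_c >= fs / 2) {
    stop_validation("carrier frequency ", f_c, " Hz must be below Nyquist (",
                    fs / 2, " Hz)")
  }
  if (length(epoch) < fs / f_c) {
    stop_validation("epoch shorter than one carrier period (", ceiling(fs / f_c),
                    " samples needed, got ", length(epoch), ")")
  }
  if (all(epoch == 0)) {
    stop_degenerate("estimate_phase_ml: identically zero epoch")
  }
  t <- (seq_along(epoch) - 1) / fs
  num <- sum(epoch * sin(2 * pi * f_c * t))
  den <- sum(epoch * cos(2 * pi * f_c * t))
  wrap_angle(atan2(-num, den))
}

# All per-trial signals used by families I-III: the 3 channels plus the
# SVD-aligned virtual channel, as a named list of length-n vectors.
trial_signals <- function(trial, include_aligned = TRUE) {
  sigs <- lapply(seq_len(nrow(trial$data)), function(i) trial$data[i, ])
  names(sigs) <- trial$channel_names
  if (include_aligned) sigs$aligned <- svd_align(trial)$aligned
  sigs
}

#' Build 0/pi phase-class templates from training epochs
#'
#' Per signal (each of the 3 channels plus the SVD-aligned channel) and per
#' phase class, the `k` training epochs of that class are stacked into a
#' `k x n` matrix whose dominant right singular vector, unit-normalised and
#' sign-fixed to correlate non-negatively with the class-mean epoch, is the
#' class template.
#'
#' @param training an [ssvep_dataset()] restricted to a single base frequency,
#'   with at least 2 trials per phase class.
#' @return an object of class `phase_templates`: per signal, unit-norm
#'   templates `pos` (phase 0) and `neg` (phase pi), plus the frequency and
#'   sampling rate.
#' @export
build_class_templates <- function(training) {
  if (length(training$frequencies) != 1L) {
    stop_validation("build_class_templates needs a single-frequency dataset; got ",
                    paste(training$frequencies, collapse = ", "), " Hz")
  }
  labs <- dataset_labels(training)
  for (s in c(1L, -1L)) {
    if (sum(labs$class_sign == s) < 2L) {
      stop_validation("phase class ", if (s == 1L) "0" else "pi",
                      " has fewer than 2 training trials")
    }
  }
  sig_list <- lapply(training$trials, trial_signals)
  signal_names <- names(sig_list[[1]])
  templates <- lapply(signal_names, function(sn) {
    per_class <- lapply(c(pos = 1L, neg = -1L), function(s) {
      E <- do.call(rbind, lapply(sig_list[labs$class_sign == s],
                                 function(x) x[[sn]]))
      if (all(abs(E - mean(E)) < 1e-300) || all(E == 0)) {
        stop_degenerate("zero-variance class matrix for signal ", sn)
      }
      dec <- svd(E, nu = 0, nv = 1)
      tmpl <- dec$v[, 1]
      tmpl <- fix_sign(tmpl, colMeans(E))
      tmpl / sqrt(sum(tmpl^2))
    })
    per_class
  })
  names(templates) <- signal_names
  structure(list(templates = templates, signal_names = signal_names,
                 frequency = training$frequencies, fs = training$fs),
            class = "phase_templates")
}

#' Correlate a trial's signals with the phase-class templates
#'
#' Two features per signal: the Pearson correlation of the epoch with the
#' phase-0 and phase-pi class templates. Over the 3 channels plus the aligned
#' channel this yields 8 features.
#'
#' @param trial an [ssvep_trial()].
#' @param templates a [build_class_templates()] result fitted on training
#'   trials only.
#' @return named numeric vector of length `2 * length(signals)`.
#' @export
correlate_with_templates <- function(trial, templates) {
  sigs <- trial_signals(trial)
  feats <- unlist(lapply(templates$signal_names, function(sn) {
    x <- sigs[[sn]]
    if (stats::sd(x) == 0) {
      stop_degenerate("zero-variance epoch for signal ", sn)
    }
    c(stats::cor(x, templates$templates[[sn]]$pos),
      stats::cor(x, templates$templates[[sn]]$neg))
  }))
  names(feats) <- as.vector(t(outer(templates$signal_names,
                                    c("cor_pos", "cor_neg"), paste, sep = ".")))
  feats
}

# Analytic signal by the frequency-domain Hilbert transform: double the
# positive frequencies, zero the negative ones (DC and Nyquist untouched).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Unit-norm quadrature of a template: the imaginary part of its analytic
# signal. For a sinusoidal template this is the 90-degree shifted carrier, so
# the template-phase feature reduces to the ML carrier-phase estimate.
template_quadrature <- function(p) {
  q <- Im(analytic_signal(p))
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop_degenerate("template has a degenerate (zero) quadrature")
  q / nq
}

#' Phase of a trial's signals relative to the phase-class templates
#'
#' For each class template `p` with unit-norm quadrature `q`, the feature is
#' `atan2(-<epoch, q>, <epoch, p>)` wrapped to (-pi, pi] — the ML phase of the
#' epoch using the template (instead of the raw carrier) as reference. Two
#' features per signal, 8 in total.
#'
#' @inheritParams correlate_with_templates
#' @return named numeric vector of wrapped phases, length
#'   `2 * length(signals)`.
#' @export
phase_vs_templates <- function(trial, templates) {
  sigs <- trial_signals(trial)
  feats <- unlist(lapply(templates$signal_names, function(sn) {
    x <- sigs[[sn]]
    if (stats::sd(x) == 0) {
      stop_degenerate("zero-variance epoch for signal ", sn)
    }
    vapply(c("pos", "neg"), function(cl) {
      p <- templates$templates[[sn]][[cl]]
      q <- template_quadrature(p)
      wrap_angle(atan2(-sum(x * q), sum(x * p)))
    }, numeric(1))
  }))
  names(feats) <- as.vector(t(outer(templates$signal_names,
                                    c("phase_pos", "phase_neg"), paste, sep = ".")))
  feats
}

#' Average an epoch's consecutive one-period segments
#'
#' Cuts the epoch into consecutive non-overlapping segments of one stimulation
#' period (`x = floor(fs / f_c)` samples) starting at onset, discards trailing
#' leftover samples, and averages the segments. At 512 Hz with 256-sample
#' epochs this yields 6 segments of 42 samples at 12 Hz and 7 segments of 34
#' samples at 15 Hz.
#'
#' @param epoch numeric vector (one channel).
#' @param f_c stimulation frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `floor(fs / f_c)` with attribute
#'   `n_segments`.
#' @export
average_period_segments <- function(epoch, f_c, fs) {
  x <- floor(fs / f_c)
  if (length(epoch) < x) {
    stop_validation("epoch (", length(epoch),
                    " samples) shorter than one period (", x, " samples)")
  }
  k <- floor(length(epoch) / x)
  seg <- matrix(epoch[seq_len(k * x)], nrow = x, ncol = k)
  out <- rowMeans(seg)
  attr(out, "n_segments") <- k
  out
}

#' Select per-channel reference segments from training data
#'
#' For every training trial and channel, the averaged one-period segment is
#' computed and the Pearson correlation matrix `R[i, j]` between all pairs of
#' averaged segments is formed. Five reference segments per channel are then
#' selected by:
#' \itemize{
#'   \item the column of `R` whose correlation with the +/-1 phase-class label
#'     vector has the largest absolute value;
#'   \item per phase class, the same-class column holding the (lower-)median
#'     rank of the mean within-class correlations (the most "centered", i.e.
#'     representative, exemplar of its class);
#'   \item the columns of maximal and minimal standard deviation (computed
#'     excluding the diagonal).
#' }
#' Ties break to the lowest trial index with a warning.
#'
#' @param training an [ssvep_dataset()] restricted to one base frequency with
#'   at least 4 trials and both phase classes present.
#' @return an object of class `segment_references`: per channel, a 5-column
#'   matrix of reference segments plus the selected trial indices and the
#'   selection rule names.
#' @export
build_segment_references <- function(training) {
  if (length(training$frequencies) != 1L) {
    stop_validation("build_segment_references needs a single-frequency dataset")
  }
  labs <- dataset_labels(training)
  if (!all(c(-1L, 1L) %in% labs$class_sign)) {
    stop_validation("both phase classes must be present in the training set")
  }
  if (nrow(labs) < 4L) {
    stop_validation("need at least 4 training trials, got ", nrow(labs))
  }
  f_c <- training$frequencies
  fs <- training$fs
  ch_names <- training$trials[[1]]$channel_names
  y <- labs$class_sign
  per_channel <- lapply(seq_along(ch_names), function(ci) {
    S <- vapply(training$trials,
                function(t) as.numeric(average_period_segments(t$data[ci, ], f_c, fs)),
                numeric(floor(fs / f_c)))
    if (any(apply(S, 2, stats::sd) == 0)) {
      stop_degenerate("zero-variance averaged segment in channel ", ch_names[ci])
    }
    R <- suppressWarnings(stats::cor(S))
    sel <- select_reference_columns(R, y)
    list(references = S[, sel$index, drop = FALSE],
         index = sel$index, rule = sel$rule)
  })
  names(per_channel) <- ch_names
  structure(list(channels = per_channel, channel_names = ch_names,
                 frequency = f_c, fs = fs,
                 period_samples = floor(fs / f_c)),
            class = "segment_references")
}

# The three selection rules over the columns of the segment correlation
# matrix R (e x e) given the +/-1 label vector y. Returns 5 column indices
# in rule order: label-correlation, centered-mean per class (0 then pi),
# max-std, min-std.
select_reference_columns <- function(R, y) {
  e <- ncol(R)
  pick_min <- function(score, what) {
    winners <- which(score <= min(score) + 1e-12)
    if (length(winners) > 1L) {
      warning("tie in ", what, " reference selection; taking lowest trial index",
              call. = FALSE)
    }
    winners[1L]
  }
  pick_max <- function(score, what) pick_min(-score, what)

  # (a) column most correlated (in absolute value) with the class labels
  lab_cor <- abs(apply(R, 2, function(col) {
    if (stats::sd(col) == 0) 0 else stats::cor(col, y)
  }))
  i_label <- pick_max(lab_cor, "label-correlation")

  # (b) per class: the column holding the (lower-)median rank of the mean
  # within-class correlations -- the most "centered" exemplar of its class
  i_center <- vapply(c(1L, -1L), function(cl) {
    cols <- which(y == cl)
    m <- vapply(cols, function(j) mean(R[setdiff(cols, j), j]), numeric(1))
    mid <- m[order(m)][floor((length(m) + 1) / 2)]
    if (sum(m == mid) > 1L) {
      warning("tie in centered-mean (class ", if (cl == 1L) "0" else "pi",
              ") reference selection; taking lowest trial index", call. = FALSE)
    }
    cols[which(m == mid)[1L]]
  }, integer(1))

  # (c) max / min column standard deviation, diagonal excluded
  col_sd <- vapply(seq_len(e), function(j) stats::sd(R[-j, j]), numeric(1))
  i_sdmax <- pick_max(col_sd, "max-std")
  i_sdmin <- pick_min(col_sd, "min-std")

  list(index = c(i_label, i_center, i_sdmax, i_sdmin),
       rule = c("label_corr", "centered_mean_class0", "centered_mean_classpi",
                "max_std", "min_std"))
}

#' Correlate a trial's averaged segments with the reference segments
#'
#' Per channel, the trial's averaged one-period segment is correlated
#' (Pearson) with each of the 5 reference segments: 15 features over the
#' 3-channel occipital set.
#'
#' @param trial an [ssvep_trial()].
#' @param refs a [build_segment_references()] result fitted on training trials
#'   only.
#' @return named numeric vector of length `5 * n_channels`, each in [-1, 1].
#' @export
correlate_with_references <- function(trial, refs) {
  feats <- unlist(lapply(seq_along(refs$channel_names), function(ci) {
    s_hat <- average_period_segments(trial$data[ci, ], refs$frequency, refs$fs)
    if (stats::sd(s_hat) == 0) {
      stop_degenerate("zero-variance averaged segment in test epoch, channel ",
                      refs$channel_names[ci])
    }
    as.numeric(stats::cor(as.numeric(s_hat), refs$channels[[ci]]$references))
  }))
  names(feats) <- as.vector(t(outer(refs$channel_names,
                                    refs$channels[[1]]$rule, paste, sep = ".")))
  feats
}

#' Enumerate the 15 feature-set combinations
#'
#' All non-empty subsets of \{I, II, III, IV\}, in the canonical order: the
#' four singletons, the six pairs, the four triples, then the full set.
#'
#' @return named list `C1` ... `C15` of character vectors of feature-set ids.
#' @export
enumerate_combinations <- function() {
  combos <- list(
    C1  = "I",   C2  = "II",  C3  = "III", C4  = "IV",
    C5  = c("I", "II"),  C6  = c("I", "III"), C7  = c("I", "IV"),
    C8  = c("II", "III"), C9  = c("II", "IV"), C10 = c("III", "IV"),
    C11 = c("I", "II", "III"), C12 = c("I", "II", "IV"),
    C13 = c("I", "III", "IV"), C14 = c("II", "III", "IV"),
    C15 = c("I", "II", "III", "IV")
  )
  combos
}

# Normalise a combination argument: "C14", c("II","III","IV") or "II+III+IV".
resolve_combination <- function(combination) {
  if (is.character(combination) && length(combination) == 1L &&
      grepl("^[Cc][0-9]+$", combination)) {
    combos <- enumerate_combinations()
    key <- toupper(combination)
    if (!key %in% names(combos)) {
      stop_validation("unknown combination '", combination, "'; valid ids are C1..C15")
    }
    return(combos[[key]])
  }
  if (is.character(combination) && length(combination) == 1L &&
      grepl("\\+", combination)) {
    combination <- strsplit(combination, "\\+")[[1]]
  }
  combination <- toupper(trimws(combination))
  if (length(combination) == 0L || !all(combination %in% FEATURE_SETS)) {
    stop_validation("combination must be a non-empty subset of {I, II, III, IV}")
  }
  FEATURE_SETS[FEATURE_SETS %in% combination]
}

#' Fit the training-derived feature artifacts for a combination
#'
#' Families II and III need the phase-class templates; family IV needs the
#' reference segments; family I needs only the stimulation frequency. This
#' fits exactly the artifacts the requested combination uses, from training
#' trials only.
#'
#' @param training an [ssvep_dataset()] restricted to one base frequency.
#' @param combination a combination id (`"C14"`), explicit subset
#'   (`c("II","III","IV")`) or `"II+III+IV"` syntax.
#' @return an object of class `feature_model` holding `frequency`, `fs` and
#'   the fitted `templates` / `references` as required.
#' @export
fit_feature_model <- function(training, combination = "C15") {
  sets <- resolve_combination(combination)
  if (length(training$frequencies) != 1L) {
    stop_validation("fit_feature_model needs a single-frequency training set")
  }
  templates <- NULL
  references <- NULL
  if (any(c("II", "III") %in% sets)) templates <- build_class_templates(training)
  if ("IV" %in% sets) references <- build_segment_references(training)
  structure(list(frequency = training$frequencies, fs = training$fs,
                 sets = sets, templates = templates, references = references),
            class = "feature_model")
}

#' Extract the feature vector of a trial for a feature-set combination
#'
#' Features are concatenated in fixed order — set I, then II, III, IV; within
#' a set the signals come in channel order (Oz, O1, O2) followed by the
#' SVD-aligned channel (families I-III only). Lengths are 4 / 8 / 8 / 15 for
#' the four sets, and a combination's length is the sum over its members
#' (e.g. 31 for \{II, III, IV\}, 35 for the full set).
#'
#' @param trial an [ssvep_trial()].
#' @param model a [fit_feature_model()] result (fitted on training data only).
#' @param combination optional subset of the model's combination to extract;
#'   defaults to the model's own sets.
#' @return named numeric feature vector with attribute `layout`, a data frame
#'   of (set, signal, feature) descriptors.
#' @export
extract_features <- function(trial, model, combination = NULL) {
  if (!inherits(model, "feature_model")) {
    stop_validation("model must be a feature_model from fit_feature_model()")
  }
  sets <- if (is.null(combination)) model$sets else resolve_combination(combination)
  if (!all(sets %in% model$sets)) {
    stop_validation("feature model was not fitted for set(s): ",
                    paste(setdiff(sets, model$sets), collapse = ", "))
  }
  out <- numeric(0)
  layout <- list()
  if ("I" %in% sets) {
    sigs <- trial_signals(trial)
    f <- vapply(sigs, estimate_phase_ml, numeric(1),
                f_c = model$frequency, fs = model$fs)
    names(f) <- paste0(names(sigs), ".phase_ml")
    out <- c(out, f)
    layout[["I"]] <- data.frame(set = "I", signal = names(sigs), feature = "phase_ml")
  }
  if ("II" %in% sets) {
    if (is.null(model$templates)) stop_validation("missing fitted artifact for Method II (templates)")
    f <- correlate_with_templates(trial, model$templates)
    out <- c(out, f)
    layout[["II"]] <- data.frame(set = "II",
                                 signal = rep(model$templates$signal_names, each = 2),
                                 feature = rep(c("cor_pos", "cor_neg"), 4))
  }
  if ("III" %in% sets) {
    if (is.null(model$templates)) stop_validation("missing fitted artifact for Method III (templates)")
    f <- phase_vs_templates(trial, model$templates)
    out <- c(out, f)
    layout[["III"]] <- data.frame(set = "III",
                                  signal = rep(model$templates$signal_names, each = 2),
                                  feature = rep(c("phase_pos", "phase_neg"), 4))
  }
  if ("IV" %in% sets) {
    if (is.null(model$references)) stop_validation("missing fitted artifact for Method IV (references)")
    f <- correlate_with_references(trial, model$references)
    out <- c(out, f)
    layout[["IV"]] <- data.frame(set = "IV",
                                 signal = rep(model$references$channel_names, each = 5),
                                 feature = rep(model$references$channels[[1]]$rule, 3))
  }
  attr(out, "layout") <- do.call(rbind, layout)
  attr(out, "combination") <- sets
  out
}

#' Feature matrix for every trial of a dataset
#'
#' @param dataset an [ssvep_dataset()].
#' @param model a [fit_feature_model()] result.
#' @return numeric matrix, trials x features, with named columns.
#' @export
featurize_dataset <- function(dataset, model) {
  rows <- lapply(dataset$trials, extract_features, model = model)
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- names(rows[[1]])
  m
}
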