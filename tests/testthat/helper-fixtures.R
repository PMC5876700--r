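# Fixtures built in code: clean (noiseless) trials and small datasets.

fs_default <- 512
n_default <- 256

# One noiseless cosine-carrier trial (3 identical-gain channels, no harmonic
# unless asked for).
clean_trial <- function(frequency = 12, phase = 0, lag = 0, gains = c(1, 1, 1),
                        harmonic_gain = 0, fs = fs_default, n = n_default,
                        subject = "s01") {
  t <- (seq_len(n) - 1) / fs
  data <- t(vapply(gains, function(g) {
    g * (cos(2 * pi * frequency * t + phase + lag) +
           harmonic_gain * cos(2 * pi * 2 * frequency * t + 2 * (phase + lag)))
  }, numeric(n)))
  # probe trials may carry an arbitrary waveform phase; the label phase must
  # still be a legal 0/pi code
  label_phase <- if (isTRUE(all.equal(phase, pi))) pi else 0
  ssvep_trial(data, fs = fs, label = target_label(frequency, label_phase),
              subject = subject, channel_names = c("Oz", "O1", "O2"))
}

# Noiseless single-frequency dataset: identical clean trials per class (the
# antipodal construction).
clean_dataset <- function(frequency = 12, per_class = 15, lag = 0, ...) {
  trials <- c(
    lapply(seq_len(per_class), function(i) clean_trial(frequency, 0, lag, ...)),
    lapply(seq_len(per_class), function(i) clean_trial(frequency, pi, lag, ...))
  )
  ssvep_dataset(trials)
}

# Small noisy single-frequency synthetic dataset.
noisy_dataset <- function(frequency = 12, snr = 10, per_class = 15, seed = 42,
                          subject_count = 1) {
  cfg <- synthetic_config(frequencies = frequency, snr = snr,
                          trials_per_target = per_class,
                          subject_count = subject_count, seed = seed)
  generate_dataset(cfg)
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(ssvephase:::wrap_angle(a - b)), tol)
}

# Independent brute-force reimplementation of the three reference-segment
# selection rules, used as the oracle for build_segment_references().
brute_force_references <- function(S, y) {
  R <- cor(S)
  e <- ncol(R)
  lab <- sapply(seq_len(e), function(j) {
    if (sd(R[, j]) == 0) 0 else abs(cor(R[, j], y))
  })
  i_a <- which(lab == max(lab))[1]
  i_b <- sapply(c(1, -1), function(cl) {
    cols <- which(y == cl)
    m <- sapply(cols, function(j) mean(R[setdiff(cols, j), j]))
    cols[which(m == sort(m)[floor((length(m) + 1) / 2)])[1]]
  })
  sds <- sapply(seq_len(e), function(j) sd(R[-j, j]))
  c(i_a, i_b, which(sds == max(sds))[1], which(sds == min(sds))[1])
}
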