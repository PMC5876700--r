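# Synthetic phase/frequency-encoded SSVEP generator. Emulates the occipital
# response to sinusoidal luminance flicker: a cosine carrier at the stimulation
# frequency plus a weaker second harmonic, per-channel gain and phase lag, and
# band-limited 1/f + white Gaussian background noise at a configurable SNR.

#' Per-channel response model
#'
#' @param gain positive amplitude multiplier for the channel.
#' @param phase_lag phase offset in radians added to the stimulus phase,
#'   modelling the electrode-dependent phase of the measured SSVEP.
#' @return an object of class `channel_model`.
#' @export
channel_model <- function(gain = 1, phase_lag = 0) {
  if (!is_scalar_number(gain) || gain <= 0) {
    stop_validation("channel gain must be a positive finite number")
  }
  if (!is_scalar_number(phase_lag)) {
    stop_validation("phase_lag must be a finite number")
  }
  structure(list(gain = gain, phase_lag = phase_lag), class = "channel_model")
}

#' Configuration of the synthetic SSVEP generator
#'
#' Defaults emulate the binary phase-decoding study design: 3 occipital
#' channels at 512 Hz, 0.5-s onset-locked epochs (256 samples), targets
#' formed by crossing frequencies {12, 15} Hz with phases {0, pi} rad, and 15
#' trials per target (so 60 trials per subject, 30 per frequency).
#'
#' @param fs sampling rate in Hz.
#' @param duration epoch length in seconds; `fs * duration` must be an
#'   integer sample count.
#' @param frequencies base stimulation frequencies in Hz.
#' @param phases stimulus phases in radians (0 and pi for binary coding).
#' @param trials_per_target trials per (frequency, phase) cell per subject.
#' @param channels list of [channel_model()] objects (default emulates
#'   Oz, O1, O2 with slightly unequal gains).
#' @param channel_names names for the simulated channels.
#' @param harmonic_gain relative amplitude of the second-harmonic (2f)
#'   component of the evoked response.
#' @param snr linear power ratio of the evoked component to the background
#'   noise, both measured in the 5-20 Hz analysis band; `snr = 0` produces
#'   pure noise, `snr = Inf` noiseless trials.
#' @param noise list with elements `pink` and `white`: power fractions of the
#'   1/f-shaped and flat Gaussian noise components (they are renormalised to
#'   sum to one).
#' @param subject_lag_jitter half-width (rad) of the uniform per-channel lag
#'   jitter around each subject's common phase lag.
#' @param subject_count number of simulated subjects.
#' @param seed RNG seed used by [generate_dataset()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 512, duration = 0.5,
                             frequencies = c(12, 15), phases = c(0, pi),
                             trials_per_target = 15,
                             channels = list(channel_model(1.0, 0),
                                             channel_model(0.85, 0),
                                             channel_model(0.9, 0)),
                             channel_names = c("Oz", "O1", "O2"),
                             harmonic_gain = 0.3, snr = 10,
                             noise = list(pink = 0.8, white = 0.2),
                             subject_lag_jitter = 0.2,
                             subject_count = 1, seed = 1) {
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) {
    stop_validation("fs * duration must be an integer sample count; got ", n)
  }
  if (!is_scalar_number(snr) && !identical(snr, Inf)) {
    stop_validation("snr must be a single non-negative number (Inf allowed)")
  }
  if (snr < 0) stop_validation("snr must be >= 0")
  if (trials_per_target < 1) stop_validation("trials_per_target must be >= 1")
  if (length(channels) != length(channel_names)) {
    stop_validation("channels and channel_names must have equal length")
  }
  structure(
    list(fs = fs, duration = duration, n_samples = as.integer(round(n)),
         frequencies = frequencies, phases = phases,
         trials_per_target = as.integer(trials_per_target),
         channels = channels, channel_names = channel_names,
         harmonic_gain = harmonic_gain, snr = snr, noise = noise,
         subject_lag_jitter = subject_lag_jitter,
         subject_count = as.integer(subject_count), seed = seed),
    class = "synthetic_config"
  )
}

# Background noise for one channel, synthesized by spectral shaping directly
# in the 5-20 Hz analysis band (what survives the nominal band-pass): white
# Gaussian noise is shaped in the frequency domain with a 1/f power profile
# (pink component) or a flat profile (white component) restricted to the
# band, then mixed by power fraction. Frequency-domain synthesis avoids IIR
# edge transients, which would dominate 0.5-s epochs. Returned unscaled; the
# caller sets the power.
synth_noise_epoch <- function(n, fs, noise) {
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)                    # two-sided frequency bin index
  f_k <- k * fs / n
  band <- f_k >= 5 & f_k <= 20
  wp <- noise$pink / (noise$pink + noise$white)
  ww <- 1 - wp
  shaped <- function(profile) {
    spec <- stats::fft(stats::rnorm(n)) * profile
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x / stats::sd(x)
  }
  x <- 0
  if (wp > 0) x <- x + sqrt(wp) * shaped(ifelse(band, 1 / sqrt(f_k), 0))
  if (ww > 0) x <- x + sqrt(ww) * shaped(as.numeric(band))
  x
}

# Deterministic evoked waveform for one channel: carrier plus second harmonic
# under the cosine convention, so the ML phase estimator recovers `phase`
# when the channel lag is zero.
synth_carrier <- function(n, fs, frequency, phase, lag, gain, harmonic_gain) {
  t <- (seq_len(n) - 1) / fs
  gain * (cos(2 * pi * frequency * t + phase + lag) +
            harmonic_gain * cos(2 * pi * 2 * frequency * t + 2 * (phase + lag)))
}

#' Generate one synthetic trial
#'
#' Each channel carries
#' `gain * [cos(2 pi f t + phi + lag) + harmonic_gain * cos(2 pi 2f t + 2(phi + lag))]`
#' plus band-limited noise scaled so that the evoked-to-noise power ratio in
#' the 5-20 Hz band equals `config$snr`.
#'
#' @param config a [synthetic_config()].
#' @param label a [target_label()] whose frequency and phase are listed in
#'   `config`.
#' @param subject subject identifier stored on the trial.
#' @param lags optional numeric vector of per-channel phase lags (radians);
#'   defaults to each channel's `phase_lag`.
#' @param seed optional seed; when given, the trial is a deterministic
#'   function of the arguments (the caller's RNG state is restored).
#' @return an [ssvep_trial()] of size channels x (fs * duration).
#' @export
generate_trial <- function(config, label, subject = "s01", lags = NULL,
                           seed = NULL) {
  if (!inherits(config, "synthetic_config")) {
    stop_validation("config must be a synthetic_config")
  }
  if (!any(vapply(config$frequencies, function(f) isTRUE(all.equal(f, label$frequency)),
                  logical(1)))) {
    stop_validation("label frequency ", label$frequency,
                    " Hz not in config frequencies (",
                    paste(config$frequencies, collapse = ", "), ")")
  }
  if (!any(vapply(config$phases, function(p) isTRUE(all.equal(p, label$phase)),
                  logical(1)))) {
    stop_validation("label phase ", label$phase, " not in config phases")
  }
  if (!is.null(seed)) {
    return(with_seed(seed, generate_trial(config, label, subject, lags, seed = NULL)))
  }
  n <- config$n_samples
  nch <- length(config$channels)
  if (is.null(lags)) {
    lags <- vapply(config$channels, function(c) c$phase_lag, numeric(1))
  }
  data <- matrix(0, nrow = nch, ncol = n)
  for (c in seq_len(nch)) {
    gain <- config$channels[[c]]$gain
    sig <- synth_carrier(n, config$fs, label$frequency, label$phase,
                         lags[c], gain, config$harmonic_gain)
    p_sig <- mean(sig^2)
    if (is.infinite(config$snr)) {
      data[c, ] <- sig
    } else if (config$snr == 0) {
      nz <- synth_noise_epoch(n, config$fs, config$noise)
      # pure noise at the power the evoked response would have had
      data[c, ] <- nz * sqrt(p_sig / mean(nz^2))
    } else {
      nz <- synth_noise_epoch(n, config$fs, config$noise)
      nz <- nz * sqrt(p_sig / (config$snr * mean(nz^2)))
      data[c, ] <- sig + nz
    }
  }
  ssvep_trial(data, fs = config$fs, label = label, subject = subject,
              channel_names = config$channel_names)
}

#' Generate a full synthetic dataset
#'
#' For each subject a common stimulus-to-EEG phase lag is drawn uniformly in
#' (-pi, pi], with small independent per-channel jitter, emulating the
#' subject- and electrode-dependent phase of measured SSVEPs. Each
#' (frequency, phase) cell then receives `trials_per_target` noisy trials.
#' With the default configuration one subject yields 60 trials (2 frequencies
#' x 2 phases x 15), each 3 x 256.
#'
#' @param config a [synthetic_config()]; `config$seed` fixes the result.
#' @return an [ssvep_dataset()]; the generator configuration is recorded in
#'   `metadata`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_validation("config must be a synthetic_config")
  }
  with_seed(config$seed, {
    trials <- list()
    nch <- length(config$channels)
    for (s in seq_len(config$subject_count)) {
      subj <- sprintf("s%02d", s)
      subj_lag <- stats::runif(1, -pi, pi)
      jitter <- stats::runif(nch, -config$subject_lag_jitter,
                             config$subject_lag_jitter)
      lags <- subj_lag +
        vapply(config$channels, function(c) c$phase_lag, numeric(1)) + jitter
      for (f in config$frequencies) {
        for (p in config$phases) {
          lab <- target_label(f, p)
          for (r in seq_len(config$trials_per_target)) {
            trials[[length(trials) + 1L]] <-
              generate_trial(config, lab, subject = subj, lags = lags)
          }
        }
      }
    }
    ssvep_dataset(trials, metadata = list(
      generator = "ssvephase synthetic",
      fs = config$fs, duration = config$duration,
      frequencies = config$frequencies,
      trials_per_target = config$trials_per_target,
      harmonic_gain = config$harmonic_gain,
      snr = if (is.infinite(config$snr)) "Inf" else config$snr,
      subject_count = config$subject_count, seed = config$seed
    ))
  })
}
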