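# Signal-conditioning chain: Butterworth band-pass, decimation to the target
# rate, onset-locked epoch cropping.

#' Band-pass filter specification
#'
#' @param low_hz high-pass edge in Hz.
#' @param high_hz low-pass edge in Hz.
#' @param order Butterworth filter order.
#' @param zero_phase apply the filter forward-backward (zero net phase
#'   distortion) instead of causally.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 5, high_hz = 20, order = 4, zero_phase = TRUE) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop_validation("need 0 < low_hz < high_hz; got [", low_hz, ", ", high_hz, "]")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 family = "butterworth", zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Band-pass filter a trial
#'
#' Applies a Butterworth IIR band-pass per channel. The default is zero-phase
#' (forward-backward) application, which leaves the phase of in-band
#' components untouched; a causal mode is available via
#' `filter_spec(zero_phase = FALSE)`.
#'
#' @param trial an [ssvep_trial()].
#' @param spec a [filter_spec()]; the default is the 5-20 Hz 4th-order
#'   analysis band.
#' @return the filtered trial, same shape and metadata.
#' @export
bandpass_filter <- function(trial, spec = filter_spec()) {
  if (spec$high_hz >= trial$fs / 2) {
    stop_validation("high_hz (", spec$high_hz, ") must be below Nyquist (",
                    trial$fs / 2, ")")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (trial$fs / 2),
                       type = "pass")
  out <- trial$data
  for (c in seq_len(nrow(out))) {
    out[c, ] <- if (spec$zero_phase) {
      signal::filtfilt(bf, trial$data[c, ])
    } else {
      as.numeric(signal::filter(bf, trial$data[c, ]))
    }
  }
  ssvep_trial(out, fs = trial$fs, label = trial$label, subject = trial$subject,
              channel_names = trial$channel_names, onset_locked = trial$onset_locked)
}

#' Downsample a trial by decimation
#'
#' Keeps every (fs / target_fs)-th sample starting at the first; assumes the
#' signal is already band-limited below `target_fs / 2` (guaranteed by the
#' 20 Hz band-pass that precedes it in the standard chain).
#'
#' @param trial an [ssvep_trial()].
#' @param target_fs target sampling rate in Hz; `trial$fs` must be an integer
#'   multiple of it.
#' @return the decimated trial with updated `fs`.
#' @export
downsample <- function(trial, target_fs) {
  ratio <- trial$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop_validation("fs (", trial$fs, ") must be an integer multiple of target_fs (",
                    target_fs, ")")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(trial)
  idx <- seq(1L, ncol(trial$data), by = ratio)
  ssvep_trial(trial$data[, idx, drop = FALSE], fs = target_fs, label = trial$label,
              subject = trial$subject, channel_names = trial$channel_names,
              onset_locked = trial$onset_locked)
}

#' Crop an onset-locked epoch to its initial segment
#'
#' @param trial an onset-locked [ssvep_trial()].
#' @param duration_s seconds to retain from stimulation onset.
#' @return the trial restricted to the first `round(duration_s * fs)` samples.
#' @export
crop_epoch <- function(trial, duration_s) {
  if (!trial$onset_locked) {
    stop_validation("crop_epoch requires an onset-locked trial")
  }
  n_keep <- as.integer(round(duration_s * trial$fs))
  if (n_keep < 1L || n_keep > ncol(trial$data)) {
    stop_validation("crop duration ", duration_s, " s (", n_keep,
                    " samples) exceeds trial length ", ncol(trial$data), " samples")
  }
  if (n_keep == ncol(trial$data)) return(trial)
  ssvep_trial(trial$data[, seq_len(n_keep), drop = FALSE], fs = trial$fs,
              label = trial$label, subject = trial$subject,
              channel_names = trial$channel_names, onset_locked = trial$onset_locked)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper: band-pass filter, decimate, crop, in that order.
#'
#' @param trial an [ssvep_trial()].
#' @param spec a [filter_spec()].
#' @param target_fs sampling rate after decimation (Hz).
#' @param crop_s epoch length to retain (seconds).
#' @return the conditioned trial.
#' @export
preprocess_trial <- function(trial, spec = filter_spec(), target_fs = 512,
                             crop_s = 0.5) {
  crop_epoch(downsample(bandpass_filter(trial, spec), target_fs), crop_s)
}
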