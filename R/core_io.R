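# Domain types (target labels, trials, datasets) and the on-disk dataset
# container: a directory of plain-text trial matrices plus a JSON sidecar.

#' Create a stimulation target label
#'
#' A target is a unique combination of stimulation frequency and stimulation
#' phase. In the binary phase-decoding setting the two phases are 0 and pi
#' radians; the phase class is also encoded as a sign (+1 for phase 0, -1 for
#' phase pi) for use as a classifier label.
#'
#' @param frequency stimulation frequency in Hz.
#' @param phase stimulation phase in radians, one of 0 or pi.
#' @return an object of class `target_label` with fields `frequency`, `phase`
#'   and `class_sign`.
#' @export
#' @examples
#' target_label(12, pi)$class_sign  # -1
target_label <- function(frequency, phase) {
  if (!is_scalar_number(frequency) || frequency <= 0) {
    stop_validation("frequency must be a positive number, got ", format(frequency))
  }
  if (!is_scalar_number(phase)) {
    stop_validation("phase must be a finite number")
  }
  if (!(isTRUE(all.equal(phase, 0, tolerance = 1e-9)) ||
        isTRUE(all.equal(phase, pi, tolerance = 1e-9)))) {
    stop_validation("phase must be 0 or pi in the binary phase-coding scheme, got ",
                    format(phase))
  }
  phase <- if (abs(phase) < 1e-6) 0 else pi
  structure(
    list(
      frequency = as.numeric(frequency),
      phase = phase,
      class_sign = if (phase == 0) 1L else -1L
    ),
    class = "target_label"
  )
}

#' Create a single stimulation epoch (trial)
#'
#' A trial is a channels-by-samples matrix of EEG, locked to stimulation
#' onset, together with its sampling rate, target label, subject identifier
#' and channel names.
#'
#' @param data numeric matrix, channels x samples; all values finite.
#' @param fs sampling rate in Hz.
#' @param label a [target_label()].
#' @param subject subject identifier (character scalar).
#' @param channel_names character vector naming the rows of `data`.
#' @param onset_locked logical; `TRUE` when sample 1 is the stimulation onset.
#' @return an object of class `ssvep_trial`.
#' @export
ssvep_trial <- function(data, fs, label, subject = "s01",
                        channel_names = NULL, onset_locked = TRUE) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_validation("trial data must be a numeric matrix (channels x samples)")
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop_validation("trial data must have at least one channel and one sample")
  }
  if (!all(is.finite(data))) {
    stop_validation("trial data contains non-finite values")
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    stop_validation("fs must be a positive sampling rate in Hz")
  }
  if (!inherits(label, "target_label")) {
    stop_validation("label must be a target_label object")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop_validation("channel_names length (", length(channel_names),
                    ") does not match channel count (", nrow(data), ")")
  }
  rownames(data) <- channel_names
  structure(
    list(
      data = data,
      fs = as.numeric(fs),
      label = label,
      subject = as.character(subject),
      channel_names = as.character(channel_names),
      onset_locked = isTRUE(onset_locked)
    ),
    class = "ssvep_trial"
  )
}

#' @export
print.ssvep_trial <- function(x, ...) {
  cat(sprintf("<ssvep_trial> %d ch x %d samples @ %g Hz | %g Hz / %s rad | subject %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$label$frequency,
              format(x$label$phase, digits = 4), x$subject))
  invisible(x)
}

#' Create an SSVEP dataset
#'
#' An ordered collection of trials sharing a sampling rate and epoch length.
#'
#' @param trials list of [ssvep_trial()] objects.
#' @param metadata free-form provenance list (generator configuration or
#'   acquisition notes).
#' @return an object of class `ssvep_dataset` with fields `trials`, `fs`,
#'   `frequencies` and `metadata`.
#' @export
ssvep_dataset <- function(trials, metadata = list()) {
  if (!is.list(trials) || length(trials) == 0L) {
    stop_validation("trials must be a non-empty list of ssvep_trial objects")
  }
  ok <- vapply(trials, inherits, logical(1), what = "ssvep_trial")
  if (!all(ok)) stop_validation("all elements of trials must be ssvep_trial objects")
  fs <- vapply(trials, function(t) t$fs, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop_validation("all trials must share the same sampling rate; found ",
                    paste(unique(fs), collapse = ", "))
  }
  ns <- vapply(trials, function(t) ncol(t$data), integer(1))
  if (length(unique(ns)) != 1L) {
    stop_validation("all trials must share the same sample count; found ",
                    paste(unique(ns), collapse = ", "))
  }
  freqs <- sort(unique(vapply(trials, function(t) t$label$frequency, numeric(1))))
  structure(
    list(trials = trials, fs = fs[1], frequencies = freqs, metadata = metadata),
    class = "ssvep_dataset"
  )
}

#' @export
print.ssvep_dataset <- function(x, ...) {
  cat(sprintf("<ssvep_dataset> %d trials @ %g Hz | frequencies: %s | subjects: %s\n",
              length(x$trials), x$fs, paste(x$frequencies, collapse = ", "),
              paste(unique(dataset_subjects(x)), collapse = ", ")))
  invisible(x)
}

#' Per-trial label summaries of a dataset
#'
#' @param dataset an [ssvep_dataset()].
#' @return `dataset_labels`: data frame with one row per trial (frequency,
#'   phase, class_sign, subject). `dataset_subjects`: character vector of
#'   per-trial subject ids.
#' @export
dataset_labels <- function(dataset) {
  data.frame(
    frequency = vapply(dataset$trials, function(t) t$label$frequency, numeric(1)),
    phase = vapply(dataset$trials, function(t) t$label$phase, numeric(1)),
    class_sign = vapply(dataset$trials, function(t) t$label$class_sign, integer(1)),
    subject = vapply(dataset$trials, function(t) t$subject, character(1))
  )
}

#' @rdname dataset_labels
#' @export
dataset_subjects <- function(dataset) {
  vapply(dataset$trials, function(t) t$subject, character(1))
}

#' Subset a dataset
#'
#' `split_by_frequency` keeps trials of one base frequency;
#' `split_by_subject` keeps one subject's trials.
#'
#' @param dataset an [ssvep_dataset()].
#' @param frequency base frequency in Hz.
#' @param subject subject identifier.
#' @return an [ssvep_dataset()] with the matching trials, in original order.
#' @export
split_by_frequency <- function(dataset, frequency) {
  keep <- vapply(dataset$trials, function(t) {
    isTRUE(all.equal(t$label$frequency, frequency))
  }, logical(1))
  if (!any(keep)) {
    stop_validation("no trials at frequency ", frequency, " Hz; available: ",
                    paste(dataset$frequencies, collapse = ", "))
  }
  ssvep_dataset(dataset$trials[keep], metadata = dataset$metadata)
}

#' @rdname split_by_frequency
#' @export
split_by_subject <- function(dataset, subject) {
  keep <- dataset_subjects(dataset) == subject
  if (!any(keep)) {
    stop_validation("no trials for subject '", subject, "'")
  }
  ssvep_dataset(dataset$trials[keep], metadata = dataset$metadata)
}

#' Write a dataset to a directory container
#'
#' The container is a directory holding one comma-delimited text matrix per
#' trial (rows = channels, columns = samples) named `trial_0000.csv`,
#' `trial_0001.csv`, ... plus a `metadata.json` sidecar recording the sampling
#' rate, channel names and per-trial labels. The format round-trips losslessly
#' up to numeric text precision.
#'
#' @param dataset an [ssvep_dataset()].
#' @param path directory to create (or reuse).
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "ssvep_dataset")) {
    stop_validation("dataset must be an ssvep_dataset")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_io("cannot create directory: ", path)
  files <- sprintf("trial_%04d.csv", seq_along(dataset$trials) - 1L)
  for (i in seq_along(dataset$trials)) {
    m <- dataset$trials[[i]]$data
    txt <- apply(m, 1L, function(row) paste(format(row, digits = 17, trim = TRUE,
                                                   scientific = TRUE),
                                            collapse = ","))
    writeLines(txt, file.path(path, files[i]))
  }
  sidecar <- list(
    fs = dataset$fs,
    channel_names = dataset$trials[[1]]$channel_names,
    trials = lapply(seq_along(dataset$trials), function(i) {
      t <- dataset$trials[[i]]
      list(file = files[i], frequency = t$label$frequency,
           phase = t$label$phase, subject = t$subject)
    }),
    metadata = dataset$metadata
  )
  jsonlite::write_json(sidecar, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset from a directory container
#'
#' @param path directory written by [write_dataset()].
#' @param strict validate that every phase label is 0 or pi (default `TRUE`).
#' @return an [ssvep_dataset()], trials in sidecar order.
#' @export
read_dataset <- function(path, strict = TRUE) {
  sidecar_path <- file.path(path, "metadata.json")
  if (!file.exists(sidecar_path)) {
    stop_io("no metadata.json sidecar found in: ", path)
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  fs <- as.numeric(sidecar$fs)
  channel_names <- as.character(unlist(sidecar$channel_names))
  trials <- lapply(sidecar$trials, function(entry) {
    f <- file.path(path, entry$file)
    if (!file.exists(f)) {
      stop_io("trial matrix file referenced by sidecar is missing: ", entry$file)
    }
    rows <- readLines(f)
    m <- do.call(rbind, lapply(strsplit(rows, ","), as.numeric))
    phase <- as.numeric(entry$phase)
    if (strict &&
        !(isTRUE(all.equal(phase, 0, tolerance = 1e-9)) ||
          isTRUE(all.equal(phase, pi, tolerance = 1e-9)))) {
      stop_validation("phase label outside {0, pi} in strict mode: ", phase)
    }
    ssvep_trial(m, fs = fs,
                label = target_label(as.numeric(entry$frequency), phase),
                subject = as.character(entry$subject),
                channel_names = channel_names)
  })
  md <- if (is.null(sidecar$metadata)) list() else sidecar$metadata
  ssvep_dataset(trials, metadata = md)
}

#' Restrict a trial to named channels
#'
#' Channel matching is case-insensitive (extended 10-20 labels such as Oz, O1,
#' O2); the returned trial has the channels in the requested order.
#'
#' @param trial an [ssvep_trial()].
#' @param names ordered channel identifiers to keep.
#' @return an [ssvep_trial()] restricted to the requested channels.
#' @export
select_channels <- function(trial, names) {
  idx <- match(tolower(names), tolower(trial$channel_names))
  if (anyNA(idx)) {
    missing <- names[is.na(idx)]
    stop_validation("unknown channel(s): ", paste(missing, collapse = ", "),
                    "; available: ", paste(trial$channel_names, collapse = ", "))
  }
  ssvep_trial(trial$data[idx, , drop = FALSE], fs = trial$fs, label = trial$label,
              subject = trial$subject, channel_names = trial$channel_names[idx],
              onset_locked = trial$onset_locked)
}
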