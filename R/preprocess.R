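#' Bandpass filter specification
#'
#' Defaults follow standard broadband EEG practice: 0.5-60 Hz, 4th-order
#' Butterworth, applied forward-backward (zero phase) so asymmetry features
#' are not phase-distorted.
#'
#' @param low_cut Lower band edge in Hz.
#' @param high_cut Upper band edge in Hz; must stay below the Nyquist
#'   frequency of the data it is applied to.
#' @param order Butterworth order (of the one-directional prototype).
#' @param zero_phase Apply forward-backward (`filtfilt`) when `TRUE`,
#'   single-pass otherwise.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 60, order = 4,
                        zero_phase = TRUE) {
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Bandpass-filter a recording
#'
#' Filters each channel independently with the Butterworth bandpass of
#' `spec`; shape and channel order are preserved (zero-phase mode changes no
#' sample counts).
#'
#' @param recording An `eeg_recording` (or plain channels x samples matrix,
#'   in which case `sampling_rate` must be given).
#' @param spec A [filter_spec()].
#' @param sampling_rate Required only for matrix input.
#' @return Object of the same type as the input, filtered.
#' @export
bandpass_filter <- function(recording, spec = filter_spec(),
                            sampling_rate = NULL) {
  is_rec <- inherits(recording, "eeg_recording")
  fs <- if (is_rec) recording$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate must be supplied for matrix input")
  if (spec$high_cut >= fs / 2)
    stop(sprintf("high_cut (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 spec$high_cut, fs / 2))
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  m <- if (is_rec) recording$signals else as.matrix(recording)
  out <- t(apply(m, 1, function(x) {
    if (spec$zero_phase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x))
  }))
  dimnames(out) <- dimnames(m)
  if (is_rec) { recording$signals <- out; recording } else out
}

#' Optional power-line notch filter
#'
#' Band-stop Butterworth around the mains frequency.  Off by default in the
#' pipeline: synthetic data carries no line noise (hardware notch filtering
#' is an acquisition-time concern).
#'
#' @param recording An `eeg_recording`.
#' @param freq Mains frequency in Hz.
#' @param width Half-width of the stop band in Hz.
#' @param order Butterworth order.
#' @return Filtered `eeg_recording`.
#' @export
notch_filter <- function(recording, freq = 60, width = 2, order = 2) {
  fs <- recording$sampling_rate
  bf <- signal::butter(order, c(freq - width, freq + width) / (fs / 2),
                       type = "stop")
  recording$signals <- t(apply(recording$signals, 1,
                               function(x) signal::filtfilt(bf, x)))
  recording
}

#' Per-channel z-score standardization
#'
#' Subtracts each channel's mean and divides by its population SD, per
#' channel within each recording (no statistics are shared across
#' recordings or subjects, so cross-validation folds cannot leak through
#' scaling).  Constant channels (SD 0) map to all zeros.  Idempotent to
#' numerical tolerance.
#'
#' @param recording An `eeg_recording` or a channels x samples matrix.
#' @return Object of the same type, standardized.
#' @export
standardize <- function(recording) {
  is_rec <- inherits(recording, "eeg_recording")
  m <- if (is_rec) recording$signals else as.matrix(recording)
  out <- t(apply(m, 1, function(x) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))
    if (s == 0) rep(0, length(x)) else (x - mu) / s
  }))
  dimnames(out) <- dimnames(m)
  if (is_rec) { recording$signals <- out; recording } else out
}

#' Preprocess a whole dataset
#'
#' Applies [bandpass_filter()] then [standardize()] to every recording of an
#' `eeg_dataset`.
#'
#' @param dataset An `eeg_dataset` from [generate_dataset()].
#' @param spec A [filter_spec()].
#' @return The dataset with filtered, standardized recordings.
#' @export
preprocess_dataset <- function(dataset, spec = filter_spec()) {
  dataset$recordings <- lapply(dataset$recordings, function(r)
    standardize(bandpass_filter(r, spec)))
  dataset
}
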