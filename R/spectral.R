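#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over Hann-windowed segments with 50%
#' overlap.  Used as the independent spectral oracle when validating the
#' generator's planted effects, and for the band-power summaries.
#'
#' @param x Numeric signal vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param seg_length Segment length in samples (default 2 s worth, capped at
#'   `length(x)`).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (power per Hz) vectors.
#' @export
welch_psd <- function(x, sampling_rate, seg_length = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_length)) seg_length <- min(n, round(2 * sampling_rate))
  seg_length <- min(seg_length, n)
  step <- max(1, floor(seg_length * (1 - overlap)))
  starts <- seq(1, n - seg_length + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_length - 1) / (seg_length - 1))
  u <- sum(win^2)
  nf <- floor(seg_length / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_length - 1)] * win
    p <- abs(fft(seg))^2 / (u * sampling_rate)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even lengths)
  inner <- 2:(nf - if (seg_length %% 2 == 0) 1 else 0)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_len(nf) - 1) * sampling_rate / seg_length, psd = psd)
}

#' Band power from a Welch PSD
#'
#' Integrates the Welch spectrum over a frequency band by the trapezoidal
#' rule.
#'
#' @param x Numeric signal vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Length-2 vector of band edges in Hz.
#' @param ... Passed to [welch_psd()].
#' @return Scalar band power.
#' @export
band_power <- function(x, sampling_rate, band, ...) {
  w <- welch_psd(x, sampling_rate, ...)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  f <- w$freq[sel]; p <- w$psd[sel]
  if (length(f) < 2) return(sum(p))
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Per-block frontal alpha asymmetry of a recording
#'
#' For every emotion block of the latent trajectory, computes the
#' right-minus-left log alpha-band power difference
#' `log P_alpha(F4) - log P_alpha(F3)` over the samples of that block,
#' together with the planted valence level.  The correlation of the two
#' columns is the planted-effect recoverability statistic.
#'
#' @param recording An `eeg_recording`.
#' @param blocks Block table from an [make_trajectory()] result.
#' @param band Alpha band edges in Hz.
#' @return Data frame with `valence_level`, `arousal_level` and
#'   `log_alpha_diff` per block.
#' @export
alpha_asymmetry_blocks <- function(recording, blocks, band = c(8, 13)) {
  fs <- recording$sampling_rate
  f3 <- recording$signals["F3", ]; f4 <- recording$signals["F4", ]
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    i0 <- max(1L, floor(blocks$start[i] * fs) + 1L)
    i1 <- min(ncol(recording$signals), floor(blocks$end[i] * fs))
    if (i1 - i0 < fs) return(NULL)  # skip blocks shorter than 1 s
    p3 <- band_power(f3[i0:i1], fs, band)
    p4 <- band_power(f4[i0:i1], fs, band)
    data.frame(valence_level = blocks$valence_level[i],
               arousal_level = blocks$arousal_level[i],
               log_alpha_diff = log(p4) - log(p3))
  })
  do.call(rbind, out)
}
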