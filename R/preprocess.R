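#' Zero-phase bandpass filter
#'
#' Frequency-domain filtering with a flat (unit-gain) passband and
#' raised-cosine transition bands centred on the requested edges, applied by
#' spectral multiplication -- zero-phase by construction, which avoids the
#' phase distortion that would bias phase-based connectivity. The transition
#' half-width adapts to the band (`min(f_low/2, bandwidth/4, 2 Hz)` at the
#' low edge and the analogous rule at the high edge), so in-band tones pass
#' at unit gain and attenuation one octave outside the passband far exceeds
#' the 20 dB contract (the response reaches zero at the end of the
#' transition).
#'
#' @param rec An `eeg_recording`.
#' @param f_low,f_high Passband edges in Hz, `0 <= f_low < f_high < fs/2`.
#'   `f_low = 0` gives a pure low-pass.
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, f_low, f_high) {
  assert_scalar_number(f_low, "f_low")
  assert_scalar_number(f_high, "f_high")
  ny <- rec$fs / 2
  if (f_low < 0 || f_low >= f_high || f_high >= ny)
    stop_invalid(sprintf(
      "passband [%g, %g] Hz must satisfy 0 <= f_low < f_high < Nyquist (%g Hz)",
      f_low, f_high, ny))
  n <- ncol(rec$data)
  f <- abs(fft_freqs(n, rec$fs))
  bw <- f_high - f_low
  gain <- rep(1, n)
  if (f_low > 0) {
    d <- min(f_low / 2, bw / 4, 2)
    gain <- gain * cosine_ramp(f, f_low - d, f_low + d)
  }
  d_hi <- min((ny - f_high) / 2, bw / 4, 2)
  gain <- gain * (1 - cosine_ramp(f, f_high - d_hi, f_high + d_hi))
  for (ch in seq_len(nrow(rec$data))) {
    X <- stats::fft(rec$data[ch, ])
    rec$data[ch, ] <- Re(stats::fft(X * gain, inverse = TRUE) / n)
  }
  rec
}

# Smooth 0 -> 1 raised-cosine ramp between a and b (0 below a, 1 above b).
cosine_ramp <- function(f, a, b) {
  out <- (f - a) / (b - a)
  out[out < 0] <- 0
  out[out > 1] <- 1
  0.5 - 0.5 * cos(pi * out)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample; the
#' output channel mean is zero at every sample, and the operation is
#' idempotent.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2)
    stop_invalid("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), `-`)
  rec
}

# Candidate 2-s/50%-overlap epoch start indices for a recording.
epoch_starts <- function(n_samples, spe, step) {
  if (n_samples < spe) return(integer(0))
  seq(1L, n_samples - spe + 1L, by = step)
}

#' Flag artifact-contaminated epochs by amplitude threshold
#'
#' A transparent stand-in for subspace-based artifact repair: every candidate
#' epoch (2-s window, 50% overlap by default) containing any sample with
#' `|x| > threshold` microvolts is flagged for exclusion.
#'
#' @param rec An `eeg_recording`.
#' @param threshold Rejection threshold in microvolts (> 0); default 150.
#' @param window Epoch length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return Logical vector over candidate epochs: `TRUE` = keep.
#' @export
reject_artifacts <- function(rec, threshold = 150, window = 2, overlap = 0.5) {
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  spe <- round(window * rec$fs)
  step <- max(1L, round(spe * (1 - overlap)))
  starts <- epoch_starts(ncol(rec$data), spe, step)
  if (length(starts) == 0L)
    stop_invalid("recording is shorter than one epoch window")
  peak <- apply(abs(rec$data), 2L, max)  # per-sample max over channels
  vapply(starts, function(s) all(peak[s:(s + spe - 1L)] <= threshold),
         logical(1))
}

#' Downsample a recording
#'
#' Anti-alias low-pass filters (zero-phase Butterworth at 0.4 * target rate)
#' then decimates. The source rate must be an integer multiple of the target
#' rate.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling rate in Hz.
#' @return The downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs) {
  assert_scalar_number(target_fs, "target_fs", positive = TRUE)
  if (target_fs >= rec$fs)
    stop_invalid("`target_fs` must be below the current sampling rate")
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop_invalid(sprintf(
      "current rate %g Hz is not an integer multiple of target %g Hz; choose a divisor",
      rec$fs, target_fs))
  q <- as.integer(round(q))
  lp <- signal::butter(4, (0.4 * target_fs) / (rec$fs / 2), type = "low")
  filtered <- t(apply(rec$data, 1L, function(x) signal::filtfilt(lp, x)))
  idx <- seq(1L, ncol(filtered), by = q)
  rec$data <- filtered[, idx, drop = FALSE]
  rownames(rec$data) <- rec$channel_labels
  rec$fs <- target_fs
  rec
}

#' Cut a recording into (optionally masked) sliding epochs
#'
#' Epochs are indexed by start time, half-open `[start, start + window)`,
#' placed every `window * (1 - overlap)` seconds. Masked-out epochs
#' (`mask = FALSE`) are dropped but remain visible through `kept_mask`.
#'
#' @param rec An `eeg_recording`.
#' @param window Epoch length in seconds (default 2).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param mask Optional logical keep-mask over candidate epochs (e.g. from
#'   [reject_artifacts()]).
#' @return An object of class `epoch_set`: list with `epochs` (array
#'   epoch x channel x sample), `fs`, `window`, `overlap`, `starts`
#'   (seconds), `kept_mask`.
#' @export
epoch_recording <- function(rec, window = 2, overlap = 0.5, mask = NULL) {
  assert_scalar_number(window, "window", positive = TRUE)
  if (overlap < 0 || overlap >= 1) stop_invalid("`overlap` must be in [0, 1)")
  spe <- round(window * rec$fs)
  if (spe < 2) stop_invalid("epoch window must span at least 2 samples")
  step <- max(1L, round(spe * (1 - overlap)))
  starts <- epoch_starts(ncol(rec$data), spe, step)
  if (length(starts) == 0L)
    stop_invalid("recording is shorter than one epoch window (empty data)")
  if (is.null(mask)) mask <- rep(TRUE, length(starts))
  if (length(mask) != length(starts))
    stop_invalid(sprintf("mask length %d does not match %d candidate epochs",
                         length(mask), length(starts)))
  keep <- which(mask)
  if (length(keep) == 0L)
    stop_invalid("all epochs are masked out (empty data)")
  epochs <- array(0, dim = c(length(keep), nrow(rec$data), spe))
  for (i in seq_along(keep)) {
    s <- starts[keep[i]]
    epochs[i, , ] <- rec$data[, s:(s + spe - 1L)]
  }
  structure(list(epochs = epochs, fs = rec$fs, window = window,
                 overlap = overlap, starts = (starts[keep] - 1L) / rec$fs,
                 kept_mask = mask, channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (window %g s, overlap %g)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$fs, x$window, x$overlap))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Fixed stage order: bandpass -> average reference -> amplitude-threshold
#' epoch rejection -> downsample -> epoch. Re-running on identical input is
#' bit-identical (no randomness).
#'
#' @param rec An `eeg_recording`.
#' @param f_low,f_high Analysis passband in Hz (defaults 0.5-45, covering the
#'   five canonical bands with margin).
#' @param threshold Epoch rejection threshold in microvolts.
#' @param target_fs Optional target sampling rate (skipped when equal to the
#'   recording's rate).
#' @param window,overlap Epoching grid (2-s windows, 50% overlap).
#' @return An `epoch_set`.
#' @export
preprocess <- function(rec, f_low = 0.5, f_high = 45, threshold = 150,
                       target_fs = NULL, window = 2, overlap = 0.5) {
  rec <- bandpass(rec, f_low, f_high)
  rec <- average_reference(rec)
  mask <- reject_artifacts(rec, threshold, window = window, overlap = overlap)
  if (!is.null(target_fs) && target_fs < rec$fs)
    rec <- downsample(rec, target_fs)
  epoch_recording(rec, window = window, overlap = overlap, mask = mask)
}
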