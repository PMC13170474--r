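#' Time-frequency representation of a recording
#'
#' Sliding-window Hanning-tapered short-time power, channel-averaged and
#' expressed in dB (`10 * log10`). Defaults: 1-s window every 0.25 s, which
#' gives 1 Hz frequency resolution; requested frequencies are mapped to the
#' nearest FFT bin.
#'
#' @param rec An `eeg_recording`.
#' @param window Window length in seconds (default 1).
#' @param step Window step in seconds (default 0.25).
#' @param freqs Frequency grid in Hz (default 1..45).
#' @return An object of class `tfr`: list with `times` (window centers, s),
#'   `freqs` (Hz), `power` (time x frequency matrix, dB), `subject_id`,
#'   `group`.
#' @export
compute_tfr <- function(rec, window = 1, step = 0.25, freqs = 1:45) {
  assert_scalar_number(window, "window", positive = TRUE)
  assert_scalar_number(step, "step", positive = TRUE)
  if (length(freqs) == 0L) stop_invalid("empty frequency grid")
  spe <- round(window * rec$fs)
  if (spe > ncol(rec$data))
    stop_invalid("window longer than the recording")
  if (any(freqs >= rec$fs / 2) || any(freqs < 0))
    stop_invalid("requested frequencies must lie in [0, Nyquist)")
  stp <- max(1L, round(step * rec$fs))
  starts <- seq(1L, ncol(rec$data) - spe + 1L, by = stp)
  taper <- hanning_taper(spe)
  binf <- (0:(spe %/% 2L)) * rec$fs / spe
  bins <- vapply(freqs, function(f) which.min(abs(binf - f)), integer(1))
  power <- matrix(0, nrow = length(starts), ncol = length(freqs))
  for (w in seq_along(starts)) {
    seg <- rec$data[, starts[w]:(starts[w] + spe - 1L), drop = FALSE]
    pw <- 0
    for (ch in seq_len(nrow(seg))) {
      X <- stats::fft(taper * seg[ch, ])
      pw <- pw + Mod(X[bins])^2
    }
    power[w, ] <- pw / nrow(seg)
  }
  power <- 10 * log10(power + .Machine$double.eps)
  structure(list(times = (starts - 1L) / rec$fs + window / 2, freqs = freqs,
                 power = power, subject_id = rec$subject_id,
                 group = rec$group),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d times x %d freqs, subject %s (%s)\n",
              length(x$times), length(x$freqs), x$subject_id, x$group))
  invisible(x)
}

# Check all TFRs share one time/frequency grid; returns subjects x pixels
# matrix plus grid dims.
stack_tfrs <- function(tfrs) {
  t0 <- tfrs[[1]]
  for (x in tfrs[-1])
    if (!isTRUE(all.equal(x$times, t0$times)) ||
        !isTRUE(all.equal(x$freqs, t0$freqs)))
      stop_invalid("all TFRs must share one time-frequency grid")
  X <- t(vapply(tfrs, function(x) as.vector(x$power),
                numeric(length(t0$power))))
  list(X = X, n_time = nrow(t0$power), n_freq = ncol(t0$power),
       times = t0$times, freqs = t0$freqs)
}
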