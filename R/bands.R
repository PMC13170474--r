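#' Canonical EEG frequency bands
#'
#' The five standard bands used throughout the pipeline: delta 1-4 Hz,
#' theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30-45 Hz. Bands are
#' half-open intervals `[f_low, f_high)` so adjacent bands partition the axis.
#'
#' @return Named list of `c(f_low, f_high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

#' @keywords internal
validate_band <- function(band, nyquist = Inf) {
  if (!is.numeric(band) || length(band) != 2L || !all(is.finite(band)))
    stop_invalid("a band must be a numeric pair c(f_low, f_high)")
  if (band[1] <= 0 || band[1] >= band[2])
    stop_invalid("band must satisfy 0 < f_low < f_high")
  if (band[2] > nyquist)
    stop_invalid(sprintf("band edge %g Hz is beyond the Nyquist frequency %g Hz",
                         band[2], nyquist))
  invisible(band)
}
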