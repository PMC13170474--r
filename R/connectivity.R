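#' Hanning-windowed Fourier coefficients of an epoch set
#'
#' Welch-style single-taper (Hanning) FFT per epoch and channel over the
#' shared 2-s / 50 %-overlap grid; 2-s windows give 0.5 Hz bin resolution.
#' One-sided spectrum (0..Nyquist).
#'
#' @param epochs An `epoch_set`.
#' @return An object of class `cross_spectra`: list with `coef` (complex
#'   array epoch x channel x bin), `freqs` (Hz), `fs`, `window`.
#' @export
windowed_fourier <- function(epochs) {
  if (!inherits(epochs, "epoch_set")) stop_invalid("`epochs` must be an epoch_set")
  d <- dim(epochs$epochs)
  if (d[1] < 1) stop_invalid("no epochs (empty data)")
  spe <- d[3]
  taper <- hanning_taper(spe)
  nbin <- spe %/% 2L + 1L
  coef <- array(complex(real = 0), dim = c(d[1], d[2], nbin))
  for (e in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      coef[e, ch, ] <- stats::fft(taper * epochs$epochs[e, ch, ])[seq_len(nbin)]
  freqs <- (seq_len(nbin) - 1L) * epochs$fs / spe
  structure(list(coef = coef, freqs = freqs, fs = epochs$fs,
                 window = epochs$window, taper = "hanning",
                 channel_labels = epochs$channel_labels),
            class = "cross_spectra")
}

band_bins <- function(cs, band) {
  validate_band(band, nyquist = max(cs$freqs))
  sel <- which(cs$freqs >= band[1] & cs$freqs < band[2])
  if (length(sel) == 0L)
    stop_invalid(sprintf("band [%g, %g) Hz contains no frequency bins", band[1], band[2]))
  sel
}

new_connectivity <- function(values, band, metric, gated = FALSE, labels = NULL) {
  diag(values) <- 0
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  structure(list(values = values, band = band, metric = metric, gated = gated),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d x %d, band [%g, %g) Hz%s\n",
              x$metric, nrow(x$values), ncol(x$values), x$band[1], x$band[2],
              if (x$gated) ", PLV-gated" else ""))
  invisible(x)
}

# Per-pair, per-bin PLV and wPLI over epochs for a set of bins, computed in
# one pass. Returns list(plv, wpli): n x n matrices of band (bin-mean) values.
pairwise_phase_metrics <- function(coef, bins) {
  nch <- dim(coef)[2]
  nep <- dim(coef)[1]
  plv <- matrix(0, nch, nch)
  wpli <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1L)) {
    zi <- coef[, i, bins, drop = FALSE]
    dim(zi) <- c(nep, length(bins))
    for (j in (i + 1L):nch) {
      zj <- coef[, j, bins, drop = FALSE]
      dim(zj) <- c(nep, length(bins))
      z <- zi * Conj(zj)
      mod <- Mod(z)
      unit <- z / ifelse(mod > 0, mod, 1)
      plv_bin <- Mod(colSums(unit)) / nep
      imz <- Im(z)
      # rounding guard: a purely real cross-spectrum (zero-lag mixing) leaves
      # Im() as O(eps) noise; treat it as exactly zero rather than letting a
      # noise/noise ratio leak into the index
      imz[abs(imz) < 1e-12 * mod] <- 0
      num <- abs(.colSums(imz, nep, length(bins)))
      den <- .colSums(abs(imz), nep, length(bins))
      wpli_bin <- ifelse(den > 0, num / den, 0)
      plv[i, j] <- plv[j, i] <- mean(plv_bin)
      wpli[i, j] <- wpli[j, i] <- mean(wpli_bin)
    }
  }
  list(plv = plv, wpli = wpli)
}

#' Phase-locking value matrix
#'
#' Per channel pair: the modulus of the epoch-mean unit-normalized
#' cross-spectral phasor, per frequency bin, averaged over the band's bins
#' (half-open `[f_low, f_high)`). Sensitive to zero-lag (volume-conducted)
#' coupling; used to gate the wPLI.
#'
#' @param cs A `cross_spectra` from [windowed_fourier()].
#' @param band `c(f_low, f_high)` in Hz.
#' @return A `connectivity_matrix` (symmetric, zero diagonal, values in
#'   `[0, 1]`).
#' @export
plv_matrix <- function(cs, band) {
  bins <- band_bins(cs, band)
  m <- pairwise_phase_metrics(cs$coef, bins)
  new_connectivity(m$plv, band, "PLV", labels = cs$channel_labels)
}

#' Weighted phase lag index matrix
#'
#' Per channel pair and frequency bin:
#' `|sum_epochs Im(S_xy)| / sum_epochs |Im(S_xy)|` (defined as 0 when the
#' denominator vanishes), then averaged over the band's bins. The imaginary
#' cross-spectrum is blind to zero-lag mixing, which is what makes the wPLI
#' robust to volume conduction. No debiasing term is applied.
#'
#' @inheritParams plv_matrix
#' @return A `connectivity_matrix`.
#' @export
wpli_matrix <- function(cs, band) {
  bins <- band_bins(cs, band)
  m <- pairwise_phase_metrics(cs$coef, bins)
  new_connectivity(m$wpli, band, "wPLI", labels = cs$channel_labels)
}

#' Gate a wPLI matrix by PLV
#'
#' Zeroes the wPLI entries of channel pairs whose PLV does not exceed the
#' threshold (default 0.1); surviving entries keep their wPLI value -- the
#' matrix is gated, not binarized.
#'
#' @param wpli,plv `connectivity_matrix` objects on the same band and shape.
#' @param threshold PLV gate (default 0.1; pairs with `PLV <= threshold` are
#'   zeroed).
#' @return The gated wPLI `connectivity_matrix` (`gated = TRUE`).
#' @export
gate_by_plv <- function(wpli, plv, threshold = 0.1) {
  if (!inherits(wpli, "connectivity_matrix") || !inherits(plv, "connectivity_matrix"))
    stop_invalid("inputs must be connectivity_matrix objects")
  if (!identical(dim(wpli$values), dim(plv$values)))
    stop_invalid("wPLI and PLV matrices have different shapes")
  if (!isTRUE(all.equal(wpli$band, plv$band)))
    stop_invalid("wPLI and PLV matrices are on different bands")
  out <- wpli
  out$values[plv$values <= threshold] <- 0
  diag(out$values) <- 0
  out$gated <- TRUE
  out
}

#' Whole-brain connectivity index
#'
#' Mean over the strict upper triangle (all `n (n - 1) / 2` channel pairs),
#' including any PLV-gated zeros, so the denominator is fixed across
#' subjects.
#'
#' @param mat A `connectivity_matrix` (n >= 2).
#' @return Scalar in `[0, 1]`.
#' @export
global_wpli <- function(mat) {
  v <- if (inherits(mat, "connectivity_matrix")) mat$values else mat
  if (nrow(v) < 2) stop_invalid("need at least 2 channels")
  mean(v[upper.tri(v)])
}

#' Per-band whole-brain connectivity profile
#'
#' The full chain for one preprocessed recording: epoch (2 s / 50 %) ->
#' Hanning-windowed Fourier -> per-band wPLI with PLV > threshold gating ->
#' whole-brain mean, for each canonical band.
#'
#' @param x An `eeg_recording` (epoched internally on the standard grid) or
#'   an `epoch_set`.
#' @param bands Named list of bands (default [eeg_bands()]).
#' @param plv_threshold PLV gate (default 0.1); `NULL` disables gating.
#' @return Named numeric vector of global wPLI per band.
#' @export
band_profile <- function(x, bands = eeg_bands(), plv_threshold = 0.1) {
  epochs <- if (inherits(x, "eeg_recording")) epoch_recording(x) else x
  cs <- windowed_fourier(epochs)
  out <- vapply(bands, function(band) {
    bins <- band_bins(cs, band)
    m <- pairwise_phase_metrics(cs$coef, bins)
    w <- new_connectivity(m$wpli, band, "wPLI", labels = cs$channel_labels)
    if (!is.null(plv_threshold)) {
      p <- new_connectivity(m$plv, band, "PLV", labels = cs$channel_labels)
      w <- gate_by_plv(w, p, plv_threshold)
    }
    global_wpli(w)
  }, numeric(1))
  names(out) <- names(bands)
  out
}
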