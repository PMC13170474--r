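#' Anesthesia state profile for the EEG generator
#'
#' A pure parameter object describing one recording state: relative linear
#' power per canonical band, target cross-channel coupling per band (the
#' fraction of band power carried by a shared, phase-lagged oscillator), and
#' the spectral slope of the 1/f^k background.
#'
#' @param name State label.
#' @param band_power_weights Named numeric vector/list over the canonical
#'   bands; relative linear power weights (dimensionless, >= 0, at least one
#'   > 0).
#' @param coupling Named numeric vector/list over the canonical bands; target
#'   coupling strength in `[0, 1]`.
#' @param noise_exponent Spectral slope k of the broadband 1/f^k background.
#' @param background_weight Relative amplitude of the broadband background
#'   (fraction of the per-band unit amplitude; small by default so band power
#'   ratios track `band_power_weights`).
#' @return An object of class `state_profile`.
#' @export
state_profile <- function(name, band_power_weights, coupling,
                          noise_exponent = 1, background_weight = 0.2) {
  bands <- names(eeg_bands())
  w <- unlist(band_power_weights)[bands]
  cp <- unlist(coupling)[bands]
  if (anyNA(w) || any(w < 0) || !any(w > 0))
    stop_invalid("band_power_weights must cover all five bands, be >= 0, with at least one > 0")
  if (anyNA(cp) || any(cp < 0) || any(cp > 1))
    stop_invalid("coupling must cover all five bands with values in [0, 1]")
  assert_scalar_number(noise_exponent, "noise_exponent")
  assert_scalar_number(background_weight, "background_weight")
  structure(list(name = name, band_power_weights = w, coupling = cp,
                 noise_exponent = noise_exponent,
                 background_weight = background_weight),
            class = "state_profile")
}

#' Default state profiles
#'
#' Built-in profiles encoding the qualitative structure the analysis assumes:
#' an awake state with gamma-dominant power and a high-frequency-dominant
#' coupling hierarchy (gamma > beta > alpha > theta > delta, gamma coupling
#' ~0.5); anesthetized states with delta-dominant power and suppressed gamma
#' coupling (~0.1 under propofol), the esketamine maintenance state retaining
#' more beta/gamma power and coupling than the propofol state; and a recovery
#' state with a delta-led, inverted coupling hierarchy
#' (delta > theta > alpha > gamma > beta).
#'
#' @return Named list of `state_profile` objects: `awake`,
#'   `esketamine_maintenance`, `propofol_maintenance`, `recovery`.
#' @export
default_profiles <- function() {
  list(
    awake = state_profile(
      "awake",
      band_power_weights = c(delta = 0.4, theta = 0.5, alpha = 0.8,
                             beta = 1.0, gamma = 1.2),
      coupling = c(delta = 0.20, theta = 0.25, alpha = 0.30,
                   beta = 0.40, gamma = 0.50),
      noise_exponent = 1.0),
    esketamine_maintenance = state_profile(
      "esketamine_maintenance",
      band_power_weights = c(delta = 1.2, theta = 0.9, alpha = 0.7,
                             beta = 0.7, gamma = 0.45),
      coupling = c(delta = 0.25, theta = 0.25, alpha = 0.15,
                   beta = 0.18, gamma = 0.20),
      noise_exponent = 1.3),
    propofol_maintenance = state_profile(
      "propofol_maintenance",
      band_power_weights = c(delta = 2.0, theta = 1.0, alpha = 0.6,
                             beta = 0.25, gamma = 0.15),
      coupling = c(delta = 0.25, theta = 0.25, alpha = 0.15,
                   beta = 0.10, gamma = 0.10),
      noise_exponent = 1.8),
    recovery = state_profile(
      "recovery",
      band_power_weights = c(delta = 1.3, theta = 1.0, alpha = 0.8,
                             beta = 0.6, gamma = 0.5),
      coupling = c(delta = 0.35, theta = 0.30, alpha = 0.27,
                   beta = 0.22, gamma = 0.25),
      noise_exponent = 1.2)
  )
}

# Unit-RMS band-limited Gaussian noise via FFT-domain masking (half-open band).
bandlimited_noise <- function(n, fs, f_low, f_high) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- abs(fft_freqs(n, fs))
  X[!(f >= f_low & f < f_high)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / sqrt(mean(y^2))
}

# Unit-RMS 1/f^k background noise (FFT-shaped white noise).
background_noise <- function(n, fs, k) {
  X <- stats::fft(stats::rnorm(n))
  f <- abs(fft_freqs(n, fs))
  scale <- ifelse(f > 0, f^(-k / 2), 0)
  y <- Re(stats::fft(X * scale, inverse = TRUE) / n)
  y / sqrt(mean(y^2))
}

# Apply a constant phase lag to a (narrowband) signal via its analytic signal.
phase_lag_signal <- function(x, phi) {
  Re(analytic_signal(x) * exp(-1i * phi))
}

#' Generate a synthetic multichannel EEG recording
#'
#' Builds a channel-by-sample signal as, per canonical band, a shared
#' band-limited oscillator injected into every channel with a fixed
#' per-channel phase lag plus independent per-channel band-limited noise, all
#' over a broadband 1/f^k background. The shared fraction of band power is the
#' profile's `coupling`; per-channel lags are drawn as
#' `sign * Uniform(pi/8, 3*pi/8)` so pair lags are bounded away from 0 and pi,
#' which makes the target wPLI controllably high (wPLI is blind to zero-lag
#' coupling). Identical seeds give bit-identical output.
#'
#' @param profile A `state_profile`.
#' @param n_channels Number of channels (>= 2).
#' @param duration Recording length in seconds (>= 4 s, i.e. two 2-s epochs).
#' @param fs Sampling rate in Hz (must exceed twice the top band edge).
#' @param seed Integer seed.
#' @param amplitude Overall RMS scale in microvolts.
#' @param ... Passed to `eeg_recording()` (subject_id, group, phase).
#' @return An `eeg_recording`.
#' @export
generate_eeg <- function(profile, n_channels = 64, duration = 60, fs = 250,
                         seed = 1, amplitude = 20, ...) {
  if (!inherits(profile, "state_profile"))
    stop_invalid("`profile` must be a state_profile")
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(duration, "duration", positive = TRUE)
  if (n_channels < 2) stop_invalid("`n_channels` must be >= 2")
  if (duration < 4) stop_invalid("`duration` must be >= 4 s (two 2-s epochs)")
  bands <- eeg_bands()
  top_edge <- max(vapply(bands, `[`, numeric(1), 2L))
  if (top_edge >= fs / 2)
    stop_invalid(sprintf("band edge %g Hz is at or beyond Nyquist (fs = %g Hz)",
                         top_edge, fs))
  n <- round(duration * fs)
  w <- profile$band_power_weights
  amp_band <- sqrt(w / sum(w))  # power weights -> amplitude scales
  with_seed(seed, {
    data <- matrix(0, nrow = n_channels, ncol = n)
    for (b in names(bands)) {
      cb <- profile$coupling[[b]]
      shared <- bandlimited_noise(n, fs, bands[[b]][1], bands[[b]][2])
      lags <- sample(c(-1, 1), n_channels, replace = TRUE) *
        stats::runif(n_channels, pi / 8, 3 * pi / 8)
      for (ch in seq_len(n_channels)) {
        comp <- sqrt(cb) * phase_lag_signal(shared, lags[ch])
        if (cb < 1)
          comp <- comp + sqrt(1 - cb) *
            bandlimited_noise(n, fs, bands[[b]][1], bands[[b]][2])
        data[ch, ] <- data[ch, ] + amp_band[[b]] * comp
      }
    }
    for (ch in seq_len(n_channels))
      data[ch, ] <- data[ch, ] + profile$background_weight *
        background_noise(n, fs, profile$noise_exponent)
    eeg_recording(amplitude * data, fs = fs, ...)
  })
}

#' Mix zero-lag volume conduction into a recording
#'
#' Replaces each channel by `(1 - leakage) * channel + leakage * mean(all
#' channels)` at every sample. The mixture is instantaneous (zero-lag) by
#' construction, so it inflates PLV but leaves wPLI untouched -- the
#' confound the wPLI is designed to reject.
#'
#' @param rec An `eeg_recording`.
#' @param leakage Mixing fraction in `[0, 1)`.
#' @return The mixed `eeg_recording`.
#' @export
mix_volume_conduction <- function(rec, leakage) {
  assert_scalar_number(leakage, "leakage")
  if (leakage < 0 || leakage >= 1)
    stop_invalid("`leakage` must be in [0, 1)")
  common <- colMeans(rec$data)
  rec$data <- (1 - leakage) * rec$data +
    leakage * matrix(common, nrow = nrow(rec$data), ncol = ncol(rec$data),
                     byrow = TRUE)
  rec
}

#' Inject transient high-amplitude artifacts
#'
#' Adds movement-like transient deflections (0.2-0.5 s raised-cosine pulses,
#' all channels) at Poisson-drawn times, returning the contaminated recording
#' together with the ground-truth event times for validating epoch rejection.
#'
#' @param rec An `eeg_recording`.
#' @param rate Expected events per minute.
#' @param amplitude Peak deflection in microvolts (> 0).
#' @param seed Integer seed.
#' @return List with elements `recording` and `events` (numeric vector of
#'   event onset times in seconds; empty when `rate = 0`).
#' @export
inject_artifacts <- function(rec, rate, amplitude, seed = 1) {
  assert_scalar_number(rate, "rate")
  if (rate < 0) stop_invalid("`rate` must be >= 0")
  assert_scalar_number(amplitude, "amplitude", positive = TRUE)
  dur <- duration(rec)
  with_seed(seed, {
    n_ev <- stats::rpois(1, rate * dur / 60)
    if (n_ev == 0)
      return(list(recording = rec, events = numeric(0)))
    onsets <- sort(stats::runif(n_ev, 0, dur))
    widths <- stats::runif(n_ev, 0.2, 0.5)
    for (e in seq_len(n_ev)) {
      i0 <- floor(onsets[e] * rec$fs) + 1L
      len <- max(2L, round(widths[e] * rec$fs))
      i1 <- min(ncol(rec$data), i0 + len - 1L)
      pulse <- amplitude * hanning_taper(i1 - i0 + 1L)
      rec$data[, i0:i1] <- sweep(rec$data[, i0:i1, drop = FALSE], 2L, pulse, `+`)
    }
    list(recording = rec, events = onsets)
  })
}
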