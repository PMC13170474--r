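# Fixtures and independent oracles shared across the suite.

# Sinusoidal recording: one row per (freq, phase) pair, in microvolts.
sin_recording <- function(freqs, phases = rep(0, length(freqs)), amps = 50,
                          fs = 250, dur = 60, ...) {
  t <- (0:(round(fs * dur) - 1)) / fs
  amps <- rep_len(amps, length(freqs))
  data <- t(mapply(function(f, ph, a) a * sin(2 * pi * f * t + ph),
                   freqs, phases, amps))
  eeg_recording(data, fs = fs, ...)
}

noise_recording <- function(n_ch = 2, fs = 250, dur = 60, sd = 20, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * round(fs * dur), sd = sd), nrow = n_ch),
                fs = fs)
}

# Brute-force ordinal pattern counter: per window, ranks via order() with an
# explicit positional tie-break. Independent of the package's vectorized path.
brute_ordinal_counts <- function(x, m, tau) {
  nw <- length(x) - (m - 1) * tau
  pats <- character(nw)
  for (w in seq_len(nw)) {
    v <- x[seq(w, by = tau, length.out = m)]
    ord <- order(v, seq_len(m))          # stable: earlier sample ranks lower
    rk <- integer(m); rk[ord] <- seq_len(m) - 1L
    pats[w] <- paste(rk, collapse = "-")
  }
  table(pats)
}

brute_pe <- function(x, m, tau) {
  counts <- as.numeric(brute_ordinal_counts(x, m, tau))
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(factorial(m))
}

# Naive per-pair wPLI/PLV from an epoch set (loop over pairs/bins/epochs).
naive_wpli <- function(epochs, band) {
  cs <- windowed_fourier(epochs)
  sel <- which(cs$freqs >= band[1] & cs$freqs < band[2])
  nch <- dim(cs$coef)[2]
  out <- matrix(0, nch, nch)
  for (i in seq_len(nch)) for (j in seq_len(nch)) {
    if (i == j) next
    vals <- numeric(length(sel))
    for (k in seq_along(sel)) {
      z <- cs$coef[, i, sel[k]] * Conj(cs$coef[, j, sel[k]])
      im <- Im(z)
      im[abs(im) < 1e-12 * Mod(z)] <- 0
      den <- sum(abs(im))
      vals[k] <- if (den > 0) abs(sum(im)) / den else 0
    }
    out[i, j] <- mean(vals)
  }
  out
}

# Synthetic TFR object on a fixed grid from a time x frequency matrix.
make_tfr <- function(mat, id = "s", grp = NA) {
  structure(list(times = seq(0.5, by = 0.25, length.out = nrow(mat)),
                 freqs = seq_len(ncol(mat)), power = mat,
                 subject_id = id, group = grp),
            class = "tfr")
}

# One seeded maintenance-phase group comparison at harness scale
# (16 channels, 60 s, subject-jittered default profiles).
maintenance_features <- function(seed, n = 17, nch = 16, dur = 60,
                                 with_tfr = FALSE, tfr_step = 0.5) {
  profs <- default_profiles()
  seeds <- derive_seeds(seed, 2 * n)
  pe_v <- matrix(NA_real_, n, 2)
  gw <- matrix(NA_real_, n, 2)
  tfrs <- list(esk = vector("list", n), pro = vector("list", n))
  for (g in 1:2) {
    prof0 <- if (g == 1) profs$esketamine_maintenance else profs$propofol_maintenance
    for (i in seq_len(n)) {
      s <- seeds[(g - 1) * n + i]
      prof <- doceeg:::with_seed(s, doceeg:::jitter_profile(prof0, 0.15))
      rec <- generate_eeg(prof, nch, dur, 250, seed = s)
      ep <- preprocess(rec)
      pe_v[i, g] <- mean(pe_timecourse(ep)$global)
      gw[i, g] <- band_profile(ep)["gamma"]
      if (with_tfr)
        tfrs[[g]][[i]] <- compute_tfr(rec, step = tfr_step)
    }
  }
  list(pe = pe_v, gamma_wpli = gw, tfrs = tfrs)
}
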