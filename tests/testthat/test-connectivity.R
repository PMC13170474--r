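test_that("windowed Fourier coefficients honor Parseval and localize tones", {
  rec <- sin_recording(c(10, 10), fs = 250, dur = 20)
  ep <- epoch_recording(rec)
  cs <- windowed_fourier(ep)
  expect_equal(diff(cs$freqs)[1], 0.5)  # 2-s windows -> 0.5 Hz bins
  pows <- Mod(cs$coef[1, 1, ])^2
  peak <- which.max(pows)
  expect_equal(cs$freqs[peak], 10)
  # the Hanning taper spreads an on-bin tone over its 3-bin main lobe
  # (relative weights 0.5/0.25/0.25); that lobe carries essentially all energy
  expect_gt(sum(pows[(peak - 1):(peak + 1)]) / sum(pows), 0.99)
  expect_equal(pows[peak] / sum(pows), 0.5^2 / (0.5^2 + 2 * 0.25^2),
               tolerance = 5e-3)

  # DC-only signal: relative to the DC coefficient, everything beyond the
  # taper's main lobe is negligible (symmetric Hanning leaks O(1/N))
  dc <- eeg_recording(matrix(3, 2, 1000), fs = 250)
  csd <- windowed_fourier(epoch_recording(dc))
  expect_lt(max(Mod(csd$coef[1, 1, csd$freqs >= 1])) / Mod(csd$coef[1, 1, 1]),
            0.01)

  # Parseval (two-sided spectrum = N x tapered time-domain energy)
  set.seed(31)
  x <- rnorm(500)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:499) / 499)
  X <- fft(taper * x)
  expect_equal(sum(Mod(X)^2), 500 * sum((taper * x)^2), tolerance = 1e-6)
  # and the one-sided stored coefficients agree with the direct FFT
  rec2 <- eeg_recording(rbind(x, x), fs = 250)
  cs2 <- windowed_fourier(epoch_recording(rec2))
  expect_equal(cs2$coef[1, 1, ], X[1:251], tolerance = 1e-9)
})

test_that("PLV hits its analytic endpoints and finite-sample null level", {
  # identical channels: PLV = 1 off-diagonal
  x <- rnorm(15000)
  recI <- eeg_recording(rbind(x, x), fs = 250)
  csI <- windowed_fourier(epoch_recording(recI))
  expect_equal(plv_matrix(csI, c(8, 13))$values[1, 2], 1, tolerance = 1e-9)

  # fixed 45-degree lag sinusoids
  rec45 <- sin_recording(c(10, 10), phases = c(0, pi / 4), fs = 250, dur = 60)
  cs45 <- windowed_fourier(epoch_recording(rec45))
  expect_gt(plv_matrix(cs45, c(8, 13))$values[1, 2], 0.99)

  # independent noise, 59 epochs: null PLV concentrates near 1/sqrt(59) = 0.13
  plv_null <- vapply(1:10, function(s) {
    cs <- windowed_fourier(epoch_recording(noise_recording(2, dur = 60,
                                                           seed = 600 + s)))
    mean(vapply(eeg_bands(), function(b) plv_matrix(cs, b)$values[1, 2],
                numeric(1)))
  }, numeric(1))
  expect_gt(mean(plv_null), 0.09)
  expect_lt(mean(plv_null), 0.15)

  # long recording (239 epochs): null PLV drops below the 0.1 gate
  cs_long <- windowed_fourier(epoch_recording(noise_recording(2, dur = 240,
                                                              seed = 77)))
  plv_long <- mean(vapply(eeg_bands(), function(b)
    plv_matrix(cs_long, b)$values[1, 2], numeric(1)))
  expect_lt(plv_long, 0.1)
})

test_that("wPLI hits its analytic endpoints and rejects zero-lag mixtures", {
  # constant 90-degree lag: every imaginary cross-term shares one sign -> 1
  rec90 <- sin_recording(c(10, 10), phases = c(0, pi / 2), fs = 250, dur = 60)
  cs90 <- windowed_fourier(epoch_recording(rec90))
  expect_equal(wpli_matrix(cs90, c(8, 13))$values[1, 2], 1)

  # pure zero-lag mixture of one source: purely real cross-spectrum -> 0
  set.seed(41)
  src <- rnorm(15000)
  mix <- eeg_recording(rbind(src, 0.6 * src), fs = 250)
  csm <- windowed_fourier(epoch_recording(mix))
  expect_lt(wpli_matrix(csm, c(8, 13))$values[1, 2], 1e-12)

  # independent noise at 59 epochs sits at the finite-sample null
  # E[wPLI] = 2/sqrt(pi * n) = 0.147, dropping below 0.1 only for >= ~128
  # epochs (verified at 239 epochs below)
  wnull <- vapply(1:20, function(s) {
    cs <- windowed_fourier(epoch_recording(noise_recording(2, dur = 60,
                                                           seed = 700 + s)))
    mean(vapply(eeg_bands(), function(b) wpli_matrix(cs, b)$values[1, 2],
                numeric(1)))
  }, numeric(1))
  expect_gt(mean(wnull), 0.12)
  expect_lt(mean(wnull), 0.18)
  cs_long <- windowed_fourier(epoch_recording(noise_recording(2, dur = 240,
                                                              seed = 78)))
  expect_lt(mean(vapply(eeg_bands(), function(b)
    wpli_matrix(cs_long, b)$values[1, 2], numeric(1))), 0.1)
})

test_that("matrix invariants hold and the vectorized wPLI equals a naive loop", {
  rec <- generate_eeg(default_profiles()$awake, 4, 20, seed = 55)
  ep <- epoch_recording(rec)
  cs <- windowed_fourier(ep)
  for (b in eeg_bands()) {
    w <- wpli_matrix(cs, b); p <- plv_matrix(cs, b)
    for (m in list(w, p)) {
      expect_equal(m$values, t(m$values))
      expect_true(all(diag(m$values) == 0))
      expect_true(all(m$values >= 0 & m$values <= 1))
    }
  }
  expect_equal(wpli_matrix(cs, c(8, 13))$values,
               naive_wpli(ep, c(8, 13)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # invariance under per-channel positive rescaling
  rec_sc <- rec
  rec_sc$data <- diag(c(0.5, 2, 7, 0.1)) %*% rec$data
  cs_sc <- windowed_fourier(epoch_recording(rec_sc))
  expect_equal(wpli_matrix(cs_sc, c(13, 30))$values,
               wpli_matrix(cs, c(13, 30))$values, tolerance = 1e-9)
  expect_equal(plv_matrix(cs_sc, c(13, 30))$values,
               plv_matrix(cs, c(13, 30))$values, tolerance = 1e-9)

  expect_error(wpli_matrix(cs, c(130, 140)), "Nyquist|bins")
  expect_error(wpli_matrix(cs, c(124.8, 124.9)), "bins")
})

test_that("PLV gating zeroes exactly the sub-threshold pairs", {
  band <- c(8, 13)
  w <- doceeg:::new_connectivity(matrix(0.5, 4, 4), band, "wPLI")
  p_hi <- doceeg:::new_connectivity(matrix(1, 4, 4), band, "PLV")
  expect_equal(gate_by_plv(w, p_hi)$values, w$values)

  p_lo <- doceeg:::new_connectivity(matrix(0.05, 4, 4), band, "PLV")
  expect_true(all(gate_by_plv(w, p_lo)$values == 0))

  set.seed(61)
  pv <- matrix(runif(16), 4, 4); pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  p_mix <- doceeg:::new_connectivity(pv, band, "PLV")
  g <- gate_by_plv(w, p_mix, threshold = 0.5)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_equal(g$values[i, j],
                 if (p_mix$values[i, j] > 0.5) 0.5 else 0)
  }
  expect_true(g$gated)
  w3 <- doceeg:::new_connectivity(matrix(0.5, 3, 3), band, "wPLI")
  expect_error(gate_by_plv(w3, p_hi), "shapes|shape")
})

test_that("the whole-brain index is the strict upper-triangle mean", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2; m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  expect_equal(global_wpli(doceeg:::new_connectivity(m, c(8, 13), "wPLI")), 0.4)

  set.seed(71)
  r <- matrix(runif(36), 6, 6); r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 0
  pairs <- combn(6, 2)
  brute <- mean(apply(pairs, 2, function(ij) r[ij[1], ij[2]]))
  expect_equal(global_wpli(doceeg:::new_connectivity(r, c(8, 13), "wPLI")),
               brute)
})

test_that("band profiles reproduce the state-dependent coupling hierarchy", {
  profs <- default_profiles()
  awake_top <- anes_top <- character(10)
  for (s in 1:10) {
    bp_a <- band_profile(preprocess(
      generate_eeg(profs$awake, 16, 60, seed = 800 + s)))
    bp_p <- band_profile(preprocess(
      generate_eeg(profs$propofol_maintenance, 16, 60, seed = 900 + s)))
    awake_top[s] <- names(which.max(bp_a))
    anes_top[s] <- names(which.max(bp_p))
  }
  expect_gte(sum(awake_top == "gamma"), 9)
  expect_gte(sum(anes_top %in% c("delta", "theta")), 9)
})
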