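test_that("TFRs are flat for stationary tones and track amplitude steps", {
  rec <- sin_recording(10, amps = 30, fs = 250, dur = 60)
  tf <- compute_tfr(rec, window = 1, step = 0.25, freqs = 1:45)
  row10 <- tf$power[, tf$freqs == 10]
  expect_lt(diff(range(row10)), 0.5)  # constant within 0.5 dB

  # amplitude x4 from t = 30 s: >= 12 dB step at the tone's frequency
  stepped <- rec
  stepped$data[, (30 * 250 + 1):15000] <- 4 * stepped$data[, (30 * 250 + 1):15000]
  tfs <- compute_tfr(stepped, window = 1, step = 0.25, freqs = 1:45)
  before <- mean(tfs$power[tfs$times < 29, tfs$freqs == 10])
  after <- mean(tfs$power[tfs$times > 31, tfs$freqs == 10])
  expect_gt(after - before, 6)

  # silence: uniform floor
  silent <- eeg_recording(matrix(0, 2, 5000), fs = 250)
  tf0 <- compute_tfr(silent)
  expect_equal(diff(range(tf0$power)), 0)

  expect_error(compute_tfr(rec, freqs = numeric(0)), "empty")
  expect_error(compute_tfr(eeg_recording(matrix(0, 2, 100), fs = 250),
                           window = 1), "longer than")
})

test_that("pointwise t-maps match the closed form and its symmetries", {
  set.seed(81)
  base <- matrix(rnorm(20 * 15), 20, 15)
  A <- lapply(1:8, function(i) make_tfr(base + rnorm(300, sd = 1)))
  expect_equal(pointwise_t(A, A), matrix(0, 20, 15))

  # A = B + constant shift with equal within-group patterns
  sigma <- 0.7
  set.seed(82)
  noise <- lapply(1:8, function(i) matrix(rnorm(300, sd = sigma), 20, 15))
  B <- lapply(noise, make_tfr)
  A2 <- lapply(noise, function(n) make_tfr(n + 1))
  tmap <- pointwise_t(A2, B)
  # identical residuals in both groups: pooled sd is the sample sd of the
  # shared noise, t = 1 / (sp * sqrt(2/8)) pixelwise
  sp <- apply(vapply(noise, as.vector, numeric(300)), 1, sd)
  expect_equal(as.vector(tmap), 1 / (sp * sqrt(2 / 8)), tolerance = 1e-10)

  expect_equal(pointwise_t(B, A2), -tmap)
  expect_error(pointwise_t(A2[1], B), "2 subjects")
  bad <- list(make_tfr(matrix(0, 5, 5)), make_tfr(matrix(0, 5, 5)))
  expect_error(pointwise_t(A2, bad), "grid")
})

test_that("cluster formation follows 4-connectivity and sign partitioning", {
  tm <- matrix(0, 5, 5)
  df <- 32
  tcrit <- qt(0.975, df)

  tm[2, 2] <- 5
  cl <- form_clusters(tm, df = df)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 5)
  expect_equal(cl[[1]]$sign, 1)

  # diagonal touch only: two separate clusters under 4-connectivity
  tm2 <- matrix(0, 5, 5); tm2[2, 2] <- 4; tm2[3, 3] <- 4
  expect_length(form_clusters(tm2, df = df), 2)
  # orthogonal touch: one cluster
  tm3 <- matrix(0, 5, 5); tm3[2, 2] <- 4; tm3[2, 3] <- 4
  cl3 <- form_clusters(tm3, df = df)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$mass, 8)

  # checkerboard of alternating signs: every pixel is its own cluster
  chk <- outer(1:6, 1:6, function(i, j) ifelse((i + j) %% 2 == 0, 4, -4))
  clc <- form_clusters(chk, df = df)
  expect_length(clc, 36)
  expect_true(all(vapply(clc, function(c) nrow(c$pixels) == 1, logical(1))))
  # flood-fill oracle: total suprathreshold pixel count conserved
  expect_equal(sum(vapply(clc, function(c) nrow(c$pixels), integer(1))),
               sum(abs(chk) > tcrit))

  expect_length(form_clusters(matrix(0, 4, 4), df = df), 0)
})

test_that("the permutation engine is seeded, bounded and label-symmetric", {
  set.seed(83)
  A <- lapply(1:8, function(i) make_tfr(matrix(rnorm(80, mean = 1.2), 10, 8)))
  B <- lapply(1:8, function(i) make_tfr(matrix(rnorm(80), 10, 8)))

  r1 <- permutation_test(A, B, n_perm = 200, seed = 11)
  r2 <- permutation_test(A, B, n_perm = 200, seed = 11)
  expect_identical(r1$null_masses, r2$null_masses)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p_cluster"),
                   vapply(r2$clusters, `[[`, numeric(1), "p_cluster"))

  ps <- vapply(r1$clusters, `[[`, numeric(1), "p_cluster")
  expect_true(all(ps >= 1 / 201 & ps <= 1))

  # label swap: t-map and cluster masses negate; p-values agree to MC error
  rs <- permutation_test(B, A, n_perm = 200, seed = 11)
  expect_equal(rs$t_map, -r1$t_map)
  expect_equal(sort(vapply(rs$clusters, `[[`, numeric(1), "mass")),
               sort(-vapply(r1$clusters, `[[`, numeric(1), "mass")))
  ps_swap <- vapply(rs$clusters, `[[`, numeric(1), "p_cluster")
  expect_lt(max(abs(sort(ps_swap) - sort(ps))), 0.06)

  # estimator floor: n_perm = 10 -> smallest achievable p = 1/11
  r10 <- permutation_test(A, B, n_perm = 10, seed = 3)
  expect_equal(min(vapply(r10$clusters, `[[`, numeric(1), "p_cluster")), 1 / 11)

  expect_error(permutation_test(A[1], B[1], n_perm = 10), "2 subjects")
})

test_that("an injected beta-range power offset is detected as a positive cluster", {
  # 17 + 17 iid dB maps with +1.5 dB added at 15-30 Hz in group A
  freqs <- 1:45
  beta_cols <- which(freqs >= 15 & freqs <= 30)
  hits <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    A <- lapply(1:17, function(i) {
      m <- matrix(rnorm(20 * 45), 20, 45); m[, beta_cols] <- m[, beta_cols] + 1.5
      make_tfr(m)
    })
    B <- lapply(1:17, function(i) make_tfr(matrix(rnorm(20 * 45), 20, 45)))
    res <- permutation_test(A, B, n_perm = 200, seed = s)
    ok <- any(vapply(res$clusters, function(cl) {
      cl$sign > 0 && cl$p_cluster < 0.05 &&
        any(res$freqs[cl$pixels[, "col"]] >= 15 &
              res$freqs[cl$pixels[, "col"]] <= 30)
    }, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})
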