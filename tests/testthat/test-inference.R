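test_that("the Shapiro-Wilk gate routes by distribution shape", {
  set.seed(91)
  gauss <- replicate(60, shapiro_route(list(rnorm(17), rnorm(17))))
  expect_gte(mean(gauss == "t_test"), 0.80)  # nominal 0.95^2 = 0.9025
  skewed <- replicate(60, shapiro_route(list(rlnorm(17, 0, 1),
                                             rlnorm(17, 0, 1))))
  expect_gte(mean(skewed == "mann_whitney"), 0.85)
  expect_error(shapiro_route(list(c(1, 2), c(1, 2, 3))), "3 values")
})

test_that("the pooled t-test reproduces the printed baseline CRS-R comparison", {
  # propofol - esketamine orientation on the published summary statistics
  res <- two_sample_t(list(mean = 6.47, sd = 2.10, n = 17),
                      list(mean = 7.65, sd = 1.84, n = 17))
  expect_equal(res$statistic, -1.742, tolerance = 5e-4)
  expect_equal(res$p_raw, 0.091, tolerance = 5e-3)
  expect_equal(res$df, 32)

  # respiratory recovery means/SDs under the same pooled formula
  res2 <- two_sample_t(list(mean = 12.02, sd = 3.88, n = 17),
                       list(mean = 17.42, sd = 4.62, n = 17))
  expect_equal(abs(res2$statistic), 3.69, tolerance = 0.005)
})

test_that("t from raw data equals t from its summary statistics", {
  set.seed(92)
  for (k in 1:5) {
    a <- rnorm(11, 2, 3); b <- rnorm(14, 1, 2)
    raw <- two_sample_t(a, b)
    summ <- two_sample_t(list(mean = mean(a), sd = sd(a), n = 11),
                         list(mean = mean(b), sd = sd(b), n = 14))
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
    expect_equal(raw$p_raw, summ$p_raw, tolerance = 1e-12)
    expect_equal(raw$effect_size, summ$effect_size, tolerance = 1e-12)
    # cross-check against the stock implementation
    expect_equal(raw$statistic,
                 unname(t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  # degenerate inputs
  eq <- two_sample_t(c(1, 1, 1), c(1, 1))
  expect_equal(c(eq$statistic, eq$p_raw, eq$effect_size), c(0, 1, 0))
  expect_error(two_sample_t(c(1, 1, 1), c(2, 2)), "degenerate")
  expect_error(two_sample_t(1, c(1, 2)), "2 values")
})

test_that("Mann-Whitney matches brute-force enumeration and its endpoints", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$effect_size, 1)

  same <- mann_whitney(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(same$effect_size, 0)

  # exact p equals full enumeration over all C(12,6) labelings
  set.seed(93)
  a <- rnorm(6); b <- rnorm(6)
  got <- mann_whitney(a, b, exact = TRUE)
  pool <- c(a, b)
  u_obs <- sum(outer(a, b, `>`))
  combos <- combn(12, 6)
  u_all <- apply(combos, 2, function(ix)
    sum(outer(pool[ix], pool[-ix], `>`)))
  # two-sided exact p: tail probability of the more extreme side, doubled
  p_low <- mean(u_all <= u_obs); p_high <- mean(u_all >= u_obs)
  p_brute <- min(1, 2 * min(p_low, p_high))
  expect_equal(got$p_raw, p_brute, tolerance = 1e-12)
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  # symmetric table
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_raw, 1)
  # complete separation: 2 / C(20, 10)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_raw,
               2 / choose(20, 10), tolerance = 1e-12)
  # the vasopressor table: enumeration oracle over k = 0..12
  tab <- matrix(c(3, 14, 9, 8), 2, byrow = TRUE)
  pr <- dhyper(0:12, 12, 22, 17)
  p_enum <- sum(pr[pr <= dhyper(3, 12, 22, 17) * (1 + 1e-7)])
  expect_equal(fisher_exact(tab)$p_raw, p_enum, tolerance = 1e-9)
  # Cramér's V from the uncorrected chi-squared
  chi2 <- unname(chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(fisher_exact(tab)$effect_size, sqrt(chi2 / 34), tolerance = 1e-12)

  # random sweep of small tables against the enumeration oracle
  set.seed(94)
  for (k in 1:50) {
    t2 <- matrix(rpois(4, 4), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    m <- sum(t2[, 1]); n2 <- sum(t2[, 2]); kk <- sum(t2[1, ])
    prk <- dhyper(0:kk, m, n2, kk)
    p_e <- sum(prk[prk <= dhyper(t2[1, 1], m, n2, kk) * (1 + 1e-7)])
    expect_equal(fisher_exact(t2)$p_raw, p_e, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Benjamini-Hochberg equals the hand-evaluated step-up rule", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  # manual step-up oracle on random vectors; order preservation; p_fdr >= p
  step_up <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(p[o] * m / (m:1)))
    adj[ro]
  }
  set.seed(95)
  for (k in 1:20) {
    p <- runif(sample(3:12, 1))
    got <- as.numeric(benjamini_hochberg(p))
    expect_equal(got, step_up(p), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
  }
})

test_that("the adjusted logistic model estimates, flags separation, and nests", {
  co <- generate_cohort(cohort_params(n_per_group = 400), seed = 101)
  fit <- fit_logistic(co)
  expect_false(fit$separation)
  cf <- fit$coefficients
  grp <- cf[cf$term == "groupesketamine", ]
  expect_equal(grp$aor, exp(grp$estimate))
  expect_true(grp$ci_low <= grp$estimate && grp$estimate <= grp$ci_high)
  expect_gt(grp$aor, 1)

  # all-true outcome: flagged, not silently estimated
  co_sep <- co; co_sep$improved <- TRUE
  expect_true(fit_logistic(co_sep)$separation)

  # EEG-augmented model vs reduced: LRT runs with df = 2
  extra <- data.frame(pe_m = rnorm(nrow(co)), gw = rnorm(nrow(co)))
  full <- fit_logistic(co, extra_covariates = extra)
  lrt <- likelihood_ratio(full, fit)
  expect_equal(lrt$df, 2)
  expect_equal(lrt$p_raw, exp(-lrt$statistic / 2), tolerance = 1e-9)
  expect_error(likelihood_ratio(fit, full), "nested")
})

test_that("the linear model recovers known effects and rejects collinearity", {
  set.seed(102)
  n <- 300
  dat <- data.frame(
    group = factor(rep(c("propofol", "esketamine"), each = n / 2),
                   levels = c("propofol", "esketamine")),
    age = rnorm(n, 50, 10),
    etiology = factor(sample(c("CVD", "TBI"), n, TRUE),
                      levels = c("CVD", "TBI")),
    crsr_baseline = rpois(n, 7))
  dat$recovery_time <- 17 - 5 * (dat$group == "esketamine") +
    0.1 * dat$age + rnorm(n, 0, 2)
  fit <- fit_linear(dat)
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "groupesketamine"], -5, tolerance = 0.15)
  expect_equal(cf$estimate[cf$term == "age"], 0.1, tolerance = 0.05)

  dat$dup <- dat$age
  expect_error(fit_linear(dat, covariates = c("group", "age", "dup")),
               "collinear")

  # pure-noise outcome: group CI covers 0 in about 95% of seeded runs
  cover <- vapply(1:60, function(s) {
    set.seed(200 + s)
    d <- dat
    d$recovery_time <- rnorm(n)
    cf <- fit_linear(d)$coefficients
    g <- cf[cf$term == "groupesketamine", ]
    g$ci_low <= 0 && 0 <= g$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("likelihood ratio matches the closed form for nested Gaussian fits", {
  set.seed(103)
  x <- rnorm(40); y <- 2 + 0.5 * x + rnorm(40)
  d <- data.frame(y = y, x = x, one = 1)
  f1 <- fit_linear(d, covariates = "x", outcome = "y")
  f0 <- stats::lm(y ~ 1, data = d)
  ll0 <- as.numeric(logLik(f0))
  chi2_hand <- 2 * (f1$log_lik - ll0)
  rss1 <- sum(residuals(f1$model)^2); rss0 <- sum((y - mean(y))^2)
  expect_equal(chi2_hand, 40 * log(rss0 / rss1), tolerance = 1e-9)

  # full == reduced: chi2 = 0, p = 1
  same <- likelihood_ratio(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
})

test_that("the cohort summary table prints the published percent style", {
  co <- generate_cohort(cohort_params(), seed = 5)
  # force the known vasopressor counts: 3/17 esketamine, 9/17 propofol
  co$norepinephrine <- "no"
  co$norepinephrine[which(co$group == "esketamine")[1:3]] <- "yes"
  co$norepinephrine[which(co$group == "propofol")[1:9]] <- "yes"
  tab <- table_one(co)
  yes_row <- tab[tab$variable == "  yes", ]
  expect_equal(yes_row$esketamine, "3 (17.65%)")
  expect_equal(yes_row$propofol, "9 (52.94%)")
  expect_true(all(c("Age (years)", "CRS-R score", "Sex") %in%
                    trimws(tab$variable)))
  # empty categories render as 0 (0%)
  co$baseline_state[co$baseline_state == "MCS+"] <- "MCS-"
  tab2 <- table_one(co)
  expect_true(all(tab2[tab2$variable == "  MCS+", c("esketamine", "propofol")]
                  == "0 (0%)") || !("  MCS+" %in% tab2$variable))

  # continuous orientation is propofol - esketamine: higher esketamine CRS-R
  # gives a negative t
  co$crsr_baseline <- ifelse(co$group == "esketamine",
                             co$crsr_baseline + 3, co$crsr_baseline)
  tab3 <- table_one(co)
  row3 <- tab3[tab3$variable == "CRS-R score", ]
  # t route: negative t (propofol - esketamine); nonparametric route:
  # rank-biserial +1 means the first (propofol) sample lies below the second
  if (row3$test == "t_test") expect_lt(row3$statistic, 0) else
    expect_gt(row3$effect_size, 0)

  expect_error(table_one(co[0, ]), "empty")
})

test_that("the ordinal state contrast codes the ladder 0-3", {
  co <- generate_cohort(cohort_params(n_per_group = 50), seed = 104)
  res <- compare_state_scores(co)
  expect_s3_class(res, "stat_result")
  # esketamine improves more often, so propofol - esketamine is negative
  expect_lt(res$statistic, 0)
})
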