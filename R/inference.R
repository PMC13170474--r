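new_stat_result <- function(test, statistic, p_raw, effect_size = NA_real_,
                            effect_name = NA_character_, summaries = NULL,
                            ...) {
  structure(list(test = test, statistic = unname(statistic),
                 p_raw = unname(p_raw), p_fdr = NA_real_,
                 effect_size = unname(effect_size), effect_name = effect_name,
                 summaries = summaries, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g", x$test,
              x$statistic, x$p_raw))
  if (!is.na(x$p_fdr)) cat(sprintf(", p_FDR = %.4g", x$p_fdr))
  if (!is.na(x$effect_size))
    cat(sprintf(", %s = %.3f", x$effect_name, x$effect_size))
  cat("\n")
  invisible(x)
}

#' Normality-gated test routing
#'
#' Applies the Shapiro-Wilk test to each group; returns `"t_test"` iff both
#' groups have Shapiro-Wilk p >= 0.05, else `"mann_whitney"`.
#'
#' @param groups List of two numeric vectors (>= 3 values each).
#' @param alpha Normality significance level (default 0.05).
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
shapiro_route <- function(groups, alpha = 0.05) {
  if (length(groups) != 2L) stop_invalid("`groups` must be a list of 2 vectors")
  for (g in groups)
    if (length(g) < 3) stop_invalid("Shapiro-Wilk needs at least 3 values per group")
  normal <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(FALSE)  # degenerate: route nonparametric
    stats::shapiro.test(g)$p.value >= alpha
  }, logical(1))
  if (all(normal)) "t_test" else "mann_whitney"
}

#' Route a two-group comparison through the normality gate
#'
#' @param a,b Numeric vectors.
#' @return A `stat_result` from [two_sample_t()] or [mann_whitney()].
#' @export
compare_groups <- function(a, b) {
  route <- tryCatch(shapiro_route(list(a, b)), error = function(e) "t_test")
  if (route == "t_test") two_sample_t(a, b) else mann_whitney(a, b)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with `df = nA + nB - 2` and Cohen's d (pooled-SD denominator).
#' Groups may be raw numeric vectors or summary statistics
#' `list(mean =, sd =, n =)`; both routes use the identical closed form, so
#' a raw-data call and its summary-statistic call agree exactly.
#' Orientation: `a - b`.
#'
#' @param a,b Numeric vectors (>= 2 values) or `list(mean, sd, n)`.
#' @return A `stat_result` with fields `statistic` (t), `p_raw` (two-tailed),
#'   `effect_size` (Cohen's d), `df`, and per-group summaries.
#' @export
two_sample_t <- function(a, b) {
  sa <- summarize_group(a); sb <- summarize_group(b)
  if (sa$n < 2 || sb$n < 2) stop_invalid("need at least 2 values per group")
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  diff <- sa$mean - sb$mean
  if (sp2 == 0) {
    if (diff != 0)
      stop_invalid("zero pooled variance with unequal means (degenerate input)")
    tt <- 0; p <- 1; d <- 0
  } else {
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    tt <- diff / se
    p <- 2 * stats::pt(-abs(tt), df)
    d <- diff / sqrt(sp2)
  }
  new_stat_result("t_test", tt, p, d, "cohens_d",
                  summaries = list(a = sa, b = sb), df = df)
}

summarize_group <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("mean", "sd", "n") %in% names(x)))
    list(mean = x$mean, sd = x$sd, n = x$n)
  } else {
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-tailed p via the normal approximation with tie correction, or exact
#' enumeration when both samples are small (`nA + nB <= 12`, no ties) or when
#' `exact = TRUE`. The statistic U counts the `(a_i, b_j)` pairs with
#' `a_i > b_j`; rank-biserial r = 1 - 2U / (nA * nB), so complete separation
#' with every `a` below every `b` gives U = 0, r = 1.
#'
#' @param a,b Numeric vectors (>= 1 value each).
#' @param exact Force exact enumeration (`TRUE`), force the normal
#'   approximation (`FALSE`), or decide by sample size and ties (`NULL`,
#'   default).
#' @return A `stat_result` with `statistic` (U for group `a`), `p_raw`,
#'   `effect_size` (rank-biserial r).
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop_invalid("need at least 1 value per group")
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- (na + nb <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  u <- unname(wt$statistic)  # pairs with a > b
  r <- 1 - 2 * u / (na * nb)
  new_stat_result("mann_whitney", u, wt$p.value, r, "rank_biserial",
                  summaries = list(
                    a = list(median = stats::median(a), n = na),
                    b = list(median = stats::median(b), n = nb)),
                  exact = exact)
}

#' Fisher's exact test on a 2x2 (or r x c) table
#'
#' Two-sided p as the sum of hypergeometric probabilities of tables (margins
#' fixed) no more probable than the observed one; Cramér's V from the
#' uncorrected chi-squared statistic, `V = sqrt(chi2 / (n * (min(r,c)-1)))`.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return A `stat_result` with `statistic` (odds ratio estimate for 2x2,
#'   `NA` otherwise), `p_raw`, `effect_size` (Cramér's V).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_invalid("`table` must contain nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_invalid("table has an all-zero margin")
  ft <- stats::fisher.test(table)
  chi2 <- suppressWarnings(stats::chisq.test(table, correct = FALSE)$statistic)
  v <- sqrt(unname(chi2) / (sum(table) * (min(dim(table)) - 1)))
  est <- if (all(dim(table) == 2L)) unname(ft$estimate) else NA_real_
  new_stat_result("fisher_exact", est, ft$p.value, v, "cramers_v",
                  summaries = list(table = table))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving with
#' the input vector. Families are declared by the caller (e.g. PE time-points
#' across the anesthesia timeline; per-phase wPLI across the five bands).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param family Optional family label (recorded as an attribute).
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p, family = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_invalid("all p-values must lie in [0, 1]")
  out <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) attr(out, "family") <- family
  out
}

model_fit_table <- function(fit, exponentiate = FALSE) {
  cf <- summary(fit)$coefficients
  est <- cf[, 1]; se <- cf[, 2]
  ci_lo <- est - stats::qnorm(0.975) * se
  ci_hi <- est + stats::qnorm(0.975) * se
  out <- data.frame(term = rownames(cf), estimate = est, se = se,
                    ci_low = ci_lo, ci_high = ci_hi,
                    p = cf[, ncol(cf)], row.names = NULL)
  if (exponentiate) {
    out$aor <- exp(est)
    out$aor_low <- exp(ci_lo)
    out$aor_high <- exp(ci_hi)
  }
  out
}

#' Confounder-adjusted logistic model for 3-month improvement
#'
#' Maximum-likelihood logistic regression of the binary improvement outcome
#' on group plus the predefined confounders (age, etiology TBI vs CVD,
#' baseline CRS-R), optionally augmented with EEG covariates. Wald 95% CIs on
#' the log-odds scale; adjusted odds ratios are the exponentiated
#' coefficients. Complete or quasi-complete separation is detected and
#' flagged rather than silently reported.
#'
#' @param cohort A `cohort_table` (or data frame with the same columns).
#' @param covariates Character vector of adjustment covariates (default
#'   `c("group", "age", "etiology", "crsr_baseline")`).
#' @param extra_covariates Optional named list/data frame of additional
#'   per-subject covariates (e.g. EEG metrics), appended to the design.
#' @param outcome Name of the binary outcome column (default `improved`).
#' @return An object of class `model_fit`: list with `coefficients` (data
#'   frame incl. aOR columns), `log_lik`, `n`, `converged`, `separation`,
#'   `model`.
#' @export
fit_logistic <- function(cohort,
                         covariates = c("group", "age", "etiology", "crsr_baseline"),
                         extra_covariates = NULL, outcome = "improved") {
  dat <- as.data.frame(cohort)
  if (!is.null(extra_covariates)) {
    extra <- as.data.frame(extra_covariates)
    stopifnot(nrow(extra) == nrow(dat))
    dat <- cbind(dat, extra)
    covariates <- c(covariates, names(extra))
  }
  y <- dat[[outcome]]
  if (length(unique(y)) < 2)
    return(structure(list(coefficients = NULL, log_lik = NA_real_,
                          n = nrow(dat), converged = FALSE, separation = TRUE,
                          outcome = outcome, covariates = covariates,
                          model = NULL),
                     class = "model_fit"))
  if (nrow(dat) <= length(covariates) + 1)
    stop_invalid("more parameters than subjects")
  form <- stats::reformulate(covariates, response = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separation <- sep_warn || any(abs(stats::coef(fit)) > 15)
  structure(list(coefficients = model_fit_table(fit, exponentiate = TRUE),
                 log_lik = as.numeric(stats::logLik(fit)),
                 df_model = attr(stats::logLik(fit), "df"),
                 n = nrow(dat), converged = fit$converged,
                 separation = separation, outcome = outcome,
                 covariates = covariates, model = fit),
            class = "model_fit")
}

#' Confounder-adjusted linear model for recovery time
#'
#' Least-squares regression of a continuous outcome (default respiratory
#' recovery time, minutes) on group plus the same confounders as the
#' logistic model, with coefficient SEs and Wald 95% CIs. A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @inheritParams fit_logistic
#' @param outcome Continuous outcome column (default `recovery_time`).
#' @return A `model_fit`.
#' @export
fit_linear <- function(cohort,
                       covariates = c("group", "age", "etiology", "crsr_baseline"),
                       outcome = "recovery_time") {
  dat <- as.data.frame(cohort)
  if (nrow(dat) <= length(covariates) + 1)
    stop_invalid("more parameters than subjects")
  form <- stats::reformulate(covariates, response = outcome)
  fit <- stats::lm(form, data = dat)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop_invalid("rank-deficient design; collinear columns: ",
                 paste(names(which(aliased)), collapse = ", "))
  structure(list(coefficients = model_fit_table(fit),
                 log_lik = as.numeric(stats::logLik(fit)),
                 df_model = attr(stats::logLik(fit), "df"),
                 n = nrow(dat), converged = TRUE, separation = FALSE,
                 outcome = outcome, covariates = covariates, model = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> outcome %s, n = %d, logLik = %.3f%s\n", x$outcome,
              x$n, x$log_lik, if (isTRUE(x$separation)) " [separation]" else ""))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test of nested model fits
#'
#' `chi2 = 2 * (logLik_full - logLik_reduced)` on `df =` difference in
#' parameter counts, with the upper-tail chi-squared p-value. The reduced
#' model's covariates must be a subset of the full model's, fitted on the
#' same rows.
#'
#' @param full,reduced `model_fit` objects.
#' @return A `stat_result` with `statistic` (chi-squared), `df`, `p_raw`.
#' @export
likelihood_ratio <- function(full, reduced) {
  if (!all(reduced$covariates %in% full$covariates))
    stop_invalid("models are not nested (reduced covariates not a subset)")
  if (full$n != reduced$n)
    stop_invalid("models were fitted on different numbers of rows")
  chi2 <- 2 * (full$log_lik - reduced$log_lik)
  df <- full$df_model - reduced$df_model
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  new_stat_result("likelihood_ratio", chi2, p, df = df)
}
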