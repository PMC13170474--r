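fmt_pct <- function(k, n) {
  if (n == 0 || k == 0) return("0 (0%)")
  sprintf("%d (%.2f%%)", k, 100 * k / n)
}

#' Baseline-characteristics summary table
#'
#' Per-variable group summaries with the routed test, statistic, p-value and
#' effect size: continuous variables go through the Shapiro-Wilk gate (pooled
#' t-test with Cohen's d when both groups look normal, reported as
#' mean +/- SD; Mann-Whitney with rank-biserial r otherwise, reported as
#' median (IQR)); categorical variables use Fisher's exact test with
#' Cramér's V and are reported as n (%) with percentages to 2 decimals.
#' Test orientation for continuous rows is propofol minus esketamine.
#'
#' @param cohort A `cohort_table`.
#' @return A data frame with one row per variable (category rows nested),
#'   columns `variable`, `esketamine`, `propofol`, `test`, `statistic`, `p`,
#'   `effect_size`.
#' @export
table_one <- function(cohort) {
  dat <- as.data.frame(cohort)
  if (nrow(dat) == 0) stop_invalid("empty cohort")
  esk <- dat[dat$group == "esketamine", ]
  pro <- dat[dat$group == "propofol", ]
  rows <- list()
  add_row <- function(variable, e = "", p = "", test = NA, statistic = NA,
                      pval = NA, eff = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, esketamine = e, propofol = p, test = test,
      statistic = statistic, p = pval, effect_size = eff,
      stringsAsFactors = FALSE)
  }
  cat_var <- function(name, column, levels) {
    counts <- vapply(levels, function(l) c(sum(esk[[column]] == l),
                                           sum(pro[[column]] == l)),
                     numeric(2))
    tab <- counts  # 2 x n_levels: rows = groups
    keep <- colSums(tab) > 0
    if (sum(keep) >= 2) {
      res <- fisher_exact(tab[, keep, drop = FALSE])
      add_row(name, test = "fisher_exact", pval = res$p_raw,
              eff = res$effect_size)
    } else {
      add_row(name, test = "fisher_exact")
    }
    for (l in levels)
      add_row(paste0("  ", l), fmt_pct(sum(esk[[column]] == l), nrow(esk)),
              fmt_pct(sum(pro[[column]] == l), nrow(pro)))
  }
  cont_var <- function(name, column) {
    a <- pro[[column]]; b <- esk[[column]]  # orientation propofol - esketamine
    res <- compare_groups(a, b)
    if (res$test == "t_test") {
      fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
    } else {
      fmt <- function(x) sprintf("%.1f (%.1f, %.1f)", stats::median(x),
                                 stats::quantile(x, 0.25),
                                 stats::quantile(x, 0.75))
    }
    add_row(name, fmt(b), fmt(a), test = res$test, statistic = res$statistic,
            pval = res$p_raw, eff = res$effect_size)
  }
  cat_var("Sex", "sex", c("M", "F"))
  cont_var("Age (years)", "age")
  cont_var("Disease duration (months)", "disease_duration")
  cat_var("Etiology", "etiology", c("TBI", "CVD"))
  cat_var("Level of consciousness", "baseline_state",
          intersect(state_levels(), unique(dat$baseline_state)))
  cont_var("CRS-R score", "crsr_baseline")
  cont_var("Surgical time (min)", "surgical_time")
  cont_var("Time for respiratory recovery (min)", "recovery_time")
  cat_var("Norepinephrine", "norepinephrine", c("yes", "no"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinal group contrast of 3-month consciousness states
#'
#' Compares the ladder-coded states (UWS = 0 < MCS- = 1 < MCS+ = 2 <
#' EMCS = 3) between groups with a two-sample pooled t-test, orientation
#' propofol minus esketamine. Treating the ordinal ladder as an interval
#' scale is statistically crude but mirrors common clinical practice for
#' this scale; interpret alongside the adjusted logistic model.
#'
#' @param cohort A `cohort_table`.
#' @param column State column, `"state_3mo"` (default) or
#'   `"baseline_state"`.
#' @return A `stat_result`.
#' @export
compare_state_scores <- function(cohort, column = "state_3mo") {
  dat <- as.data.frame(cohort)
  a <- state_score(dat[[column]][dat$group == "propofol"])
  b <- state_score(dat[[column]][dat$group == "esketamine"])
  two_sample_t(a, b)
}
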