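#' Ordered consciousness-state ladder
#'
#' The diagnostic ladder used throughout: UWS < MCS- < MCS+ < EMCS.
#' `state_score()` codes states 0-3 on that ladder.
#'
#' @return Character vector of state labels in increasing order.
#' @export
state_levels <- function() c("UWS", "MCS-", "MCS+", "EMCS")

#' @rdname state_levels
#' @param state Character vector of state labels.
#' @export
state_score <- function(state) {
  match(as.character(state), state_levels()) - 1L
}

#' Parameters of the synthetic clinical cohort
#'
#' Per-group means/SDs of the continuous variables, per-group category
#' probabilities, and the logistic model (log-odds scale) that generates the
#' 3-month "improved" flag. Defaults mirror the two-arm surgical cohort the
#' pipeline is built for: 17 subjects per arm, balanced demographics, a large
#' group effect on improvement (log-odds `log(6.84)`) and a -5.4 min adjusted
#' group effect on respiratory recovery time.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param age,crsr_baseline,surgical_time,recovery_time,disease_duration
#'   Lists with per-group `c(mean, sd)` entries named `esketamine` and
#'   `propofol`.
#' @param p_male,p_tbi,p_norepinephrine Named per-group probabilities.
#' @param state_probs Named list of per-group probability vectors over
#'   baseline states `UWS`, `MCS-`, `MCS+` (must sum to 1).
#' @param improvement_log_odds Named numeric vector with elements
#'   `intercept`, `group` (esketamine vs propofol), `age` (per year),
#'   `etiology` (TBI vs CVD) and `crsr_baseline` (per point).
#' @param recovery_covariate_effects Named numeric vector of linear effects of
#'   `age` (min/year) and `crsr_baseline` (min/point) on recovery time,
#'   applied around the pooled covariate means so the adjusted group effect
#'   equals the difference of the group means.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(
    n_per_group = 17,
    age = list(esketamine = c(46.92, 15.18), propofol = c(50.29, 14.00)),
    crsr_baseline = list(esketamine = c(7.65, 1.84), propofol = c(6.47, 2.10)),
    surgical_time = list(esketamine = c(51.92, 10.9), propofol = c(54.17, 6.28)),
    recovery_time = list(esketamine = c(12.02, 3.88), propofol = c(17.42, 4.62)),
    disease_duration = list(esketamine = c(4.5, 2.5), propofol = c(4.0, 2.5)),
    p_male = c(esketamine = 12 / 17, propofol = 10 / 17),
    p_tbi = c(esketamine = 9 / 17, propofol = 10 / 17),
    p_norepinephrine = c(esketamine = 3 / 17, propofol = 9 / 17),
    state_probs = list(esketamine = c(UWS = 10, `MCS-` = 6, `MCS+` = 1) / 17,
                       propofol = c(UWS = 13, `MCS-` = 4, `MCS+` = 0) / 17),
    improvement_log_odds = c(intercept = -2.61, group = log(6.84),
                             age = log(0.99), etiology = log(1.32),
                             crsr_baseline = log(1.28)),
    recovery_covariate_effects = c(age = 0.07, crsr_baseline = -0.28)) {
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop_invalid("`n_per_group` must be >= 2")
  cont <- list(age = age, crsr_baseline = crsr_baseline,
               surgical_time = surgical_time, recovery_time = recovery_time,
               disease_duration = disease_duration)
  for (v in names(cont)) for (g in c("esketamine", "propofol")) {
    ms <- cont[[v]][[g]]
    if (length(ms) != 2L || !all(is.finite(ms)) || ms[2] <= 0)
      stop_invalid(sprintf("`%s$%s` must be c(mean, sd) with sd > 0", v, g))
  }
  for (p in list(p_male, p_tbi, p_norepinephrine))
    if (any(p < 0 | p > 1)) stop_invalid("category probabilities must be in [0, 1]")
  for (g in names(state_probs)) {
    sp <- state_probs[[g]]
    if (any(sp < 0) || abs(sum(sp) - 1) > 1e-8)
      stop_invalid("`state_probs` must be nonnegative and sum to 1 per group")
  }
  need <- c("intercept", "group", "age", "etiology", "crsr_baseline")
  if (!all(need %in% names(improvement_log_odds)))
    stop_invalid("`improvement_log_odds` must name intercept, group, age, etiology, crsr_baseline")
  structure(list(
    n_per_group = as.integer(n_per_group), age = age,
    crsr_baseline = crsr_baseline, surgical_time = surgical_time,
    recovery_time = recovery_time, disease_duration = disease_duration,
    p_male = p_male, p_tbi = p_tbi, p_norepinephrine = p_norepinephrine,
    state_probs = state_probs, improvement_log_odds = improvement_log_odds,
    recovery_covariate_effects = recovery_covariate_effects),
    class = "cohort_params")
}

rnorm_group <- function(n, ms) stats::rnorm(n, ms[1], ms[2])

#' Generate a synthetic clinical cohort
#'
#' Draws one subject row per patient: group, age, sex, etiology, disease
#' duration, baseline state and CRS-R (integer, clamped to the scale's 0-23
#' range), surgical time, respiratory recovery time, vasopressor
#' (norepinephrine) flag, a 3-month "improved" flag drawn from the logistic
#' model in `params`, and the implied 3-month state (improvement = an upward
#' move on the UWS < MCS- < MCS+ < EMCS ladder). Identical seeds give an
#' identical table.
#'
#' @param params A `cohort_params`.
#' @param seed Integer seed.
#' @return A `data.frame` with class `cohort_table`; `group` and `etiology`
#'   are factors with reference levels `propofol` and `CVD`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  if (!inherits(params, "cohort_params"))
    stop_invalid("`params` must come from cohort_params()")
  n <- params$n_per_group
  groups <- c("esketamine", "propofol")
  with_seed(seed, {
    rows <- lapply(groups, function(g) {
      age <- rnorm_group(n, params$age[[g]])
      crsr <- pmin(23L, pmax(0L, as.integer(round(
        rnorm_group(n, params$crsr_baseline[[g]])))))
      duration <- pmax(1, round(rnorm_group(n, params$disease_duration[[g]])))
      surgical <- pmax(5, rnorm_group(n, params$surgical_time[[g]]))
      data.frame(
        group = g,
        age = age,
        sex = ifelse(stats::runif(n) < params$p_male[[g]], "M", "F"),
        etiology = ifelse(stats::runif(n) < params$p_tbi[[g]], "TBI", "CVD"),
        disease_duration = duration,
        baseline_state = sample(names(params$state_probs[[g]]), n,
                                replace = TRUE,
                                prob = params$state_probs[[g]]),
        crsr_baseline = crsr,
        surgical_time = surgical,
        stringsAsFactors = FALSE)
    })
    cohort <- do.call(rbind, rows)
    cohort$subject_id <- sprintf("S%03d", seq_len(nrow(cohort)))
    cohort$group <- factor(cohort$group, levels = c("propofol", "esketamine"))
    cohort$etiology <- factor(cohort$etiology, levels = c("CVD", "TBI"))

    # Recovery time: group mean plus covariate effects about the pooled
    # covariate means, so the covariate-adjusted group effect equals the
    # difference of the group means.
    mu_age <- mean(vapply(groups, function(g) params$age[[g]][1], numeric(1)))
    mu_crsr <- mean(vapply(groups, function(g) params$crsr_baseline[[g]][1],
                           numeric(1)))
    eff <- params$recovery_covariate_effects
    base <- ifelse(cohort$group == "esketamine",
                   params$recovery_time$esketamine[1],
                   params$recovery_time$propofol[1])
    res_sd <- ifelse(cohort$group == "esketamine",
                     params$recovery_time$esketamine[2],
                     params$recovery_time$propofol[2])
    cohort$recovery_time <- pmax(0.5,
      base + eff[["age"]] * (cohort$age - mu_age) +
        eff[["crsr_baseline"]] * (cohort$crsr_baseline - mu_crsr) +
        stats::rnorm(nrow(cohort), 0, res_sd))

    cohort$norepinephrine <- ifelse(
      stats::runif(nrow(cohort)) <
        params$p_norepinephrine[as.character(cohort$group)], "yes", "no")

    lo <- params$improvement_log_odds
    lp <- lo[["intercept"]] +
      lo[["group"]] * (cohort$group == "esketamine") +
      lo[["age"]] * cohort$age +
      lo[["etiology"]] * (cohort$etiology == "TBI") +
      lo[["crsr_baseline"]] * cohort$crsr_baseline
    cohort$improved <- stats::runif(nrow(cohort)) < stats::plogis(lp)

    # 3-month state: improvement is an upward move on the ladder
    # (one step, occasionally two, capped at EMCS).
    base_score <- state_score(cohort$baseline_state)
    up <- 1L + stats::rbinom(nrow(cohort), 1L, 0.3)
    final <- ifelse(cohort$improved,
                    pmax(pmin(3L, base_score + up), base_score + 1L),
                    base_score)
    cohort$state_3mo <- state_levels()[final + 1L]
    rownames(cohort) <- NULL
    class(cohort) <- c("cohort_table", "data.frame")
    cohort[, c("subject_id", "group", "age", "sex", "etiology",
               "disease_duration", "baseline_state", "crsr_baseline",
               "surgical_time", "recovery_time", "norepinephrine",
               "state_3mo", "improved")]
  })
}
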