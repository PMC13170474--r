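#' Pipeline configuration
#'
#' One declarative object driving the whole analysis: input mode, generator
#' parameters, preprocessing parameters, analysis parameters and seed. Every
#' stochastic stage draws its own stream from `seed` via [derive_seeds()],
#' so identical configs give identical reports.
#'
#' @param seed Master seed.
#' @param input `list(mode = "synthetic")` (default) or
#'   `list(mode = "files", eeg_paths = <character>, cohort_csv = <path>)`.
#' @param cohort [cohort_params()] for synthetic mode.
#' @param profiles Named list of state profiles (default
#'   [default_profiles()]).
#' @param n_channels,duration_s,fs Synthetic recording geometry (defaults
#'   64 channels, 60 s, 250 Hz).
#' @param subject_jitter_sd SD of the per-subject lognormal jitter applied to
#'   band power weights and coupling (inter-subject variability; default
#'   0.15).
#' @param artifact_rate,artifact_amplitude Injected artifact events/min and
#'   peak microvolts for synthetic recordings.
#' @param f_low,f_high,reject_threshold,target_fs Preprocessing parameters.
#' @param pe_m,pe_tau Permutation entropy embedding.
#' @param plv_threshold PLV gate for wPLI.
#' @param tfr_window,tfr_step,tfr_freqs TFR grid.
#' @param n_perm Cluster-test permutations (default 1000).
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1,
                            input = list(mode = "synthetic"),
                            cohort = cohort_params(),
                            profiles = default_profiles(),
                            n_channels = 64, duration_s = 60, fs = 250,
                            subject_jitter_sd = 0.15,
                            artifact_rate = 1, artifact_amplitude = 400,
                            f_low = 0.5, f_high = 45,
                            reject_threshold = 150, target_fs = NULL,
                            pe_m = 3, pe_tau = 1,
                            plv_threshold = 0.1,
                            tfr_window = 1, tfr_step = 0.25,
                            tfr_freqs = 1:45,
                            n_perm = 1000) {
  stopifnot(input$mode %in% c("synthetic", "files"))
  structure(as.list(environment()), class = "run_config")
}

# Jitter a state profile's weights/coupling for one subject.
jitter_profile <- function(profile, sd) {
  if (sd <= 0) return(profile)
  w <- profile$band_power_weights * exp(stats::rnorm(5, 0, sd))
  cp <- pmin(profile$coupling * exp(stats::rnorm(5, 0, sd)), 1)
  state_profile(profile$name, w, cp, profile$noise_exponent,
                profile$background_weight)
}

phase_profile <- function(profiles, group, phase) {
  switch(phase,
         preoperative = profiles$awake,
         maintenance = if (group == "esketamine") profiles$esketamine_maintenance
                       else profiles$propofol_maintenance,
         recovery = profiles$recovery,
         stop_invalid("unknown phase: ", phase))
}

#' Validate an EEG-file/cohort dataset before analysis
#'
#' Reads the headers of delimited EEG files, checks channel counts and
#' sampling rates are consistent, that every cohort subject has every
#' expected phase and vice versa, and returns the manifest of what will be
#' analyzed. Mismatches are explicit errors.
#'
#' @param eeg_paths Character vector of [write_eeg_txt()]-format files.
#' @param cohort A `cohort_table`.
#' @param phases Expected phases per subject.
#' @return Data frame manifest: `subject_id`, `group`, `phase`, `path`,
#'   `fs`, `n_channels`.
#' @export
validate_inputs <- function(eeg_paths, cohort,
                            phases = c("preoperative", "maintenance", "recovery")) {
  recs <- lapply(eeg_paths, read_eeg_txt)
  manifest <- data.frame(
    subject_id = vapply(recs, function(r) r$subject_id, character(1)),
    group = vapply(recs, function(r) r$group, character(1)),
    phase = vapply(recs, function(r) r$phase, character(1)),
    path = eeg_paths,
    fs = vapply(recs, function(r) r$fs, numeric(1)),
    n_channels = vapply(recs, n_channels, integer(1)),
    stringsAsFactors = FALSE)
  if (length(unique(manifest$fs)) > 1)
    stop_invalid("mismatched sampling rates across files: ",
                 paste(unique(manifest$fs), collapse = ", "))
  if (length(unique(manifest$n_channels)) > 1)
    stop_invalid("mismatched channel counts across files: ",
                 paste(unique(manifest$n_channels), collapse = ", "))
  eeg_subjects <- unique(manifest$subject_id)
  cohort_subjects <- cohort$subject_id
  missing_cohort <- setdiff(eeg_subjects, cohort_subjects)
  if (length(missing_cohort))
    stop_invalid("EEG subjects missing from the cohort table: ",
                 paste(missing_cohort, collapse = ", "))
  missing_eeg <- setdiff(cohort_subjects, eeg_subjects)
  if (length(missing_eeg))
    stop_invalid("cohort subjects with no EEG files: ",
                 paste(missing_eeg, collapse = ", "))
  for (s in eeg_subjects) {
    have <- manifest$phase[manifest$subject_id == s]
    lack <- setdiff(phases, have)
    if (length(lack))
      stop_invalid(sprintf("subject %s is missing phase(s): %s", s,
                           paste(lack, collapse = ", ")))
  }
  manifest[order(manifest$subject_id, match(manifest$phase, phases)), ]
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: obtain data (synthetic generation or file reading) ->
#' preprocess -> permutation entropy, band-wise PLV-gated wPLI and TFRs ->
#' group statistics with FDR families -> cluster-based permutation test ->
#' cohort summary and adjusted outcome models with the EEG-augmented
#' likelihood-ratio comparison. Identical configs give identical reports;
#' failures of an independent stage are recorded as warnings and later
#' stages still run.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return An object of class `run_report`: nested list with elements
#'   `config_summary`, `cohort`, `manifest`, `pe`, `wpli`, `cluster`,
#'   `table_one`, `state_contrasts`, `models`, `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "run_config"))
    stop_invalid("`config` must come from pipeline_config()")
  phases <- c("preoperative", "maintenance", "recovery")
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  seeds <- derive_seeds(config$seed, 3)
  if (config$input$mode == "synthetic") {
    cohort <- generate_cohort(config$cohort, seed = seeds[1])
    n_sub <- nrow(cohort)
    sub_seeds <- matrix(derive_seeds(seeds[2], n_sub * length(phases)),
                        nrow = n_sub)
    get_rec <- function(i, ph) {
      prof <- phase_profile(config$profiles, as.character(cohort$group[i]), ph)
      s <- sub_seeds[i, match(ph, phases)]
      prof <- with_seed(s, jitter_profile(prof, config$subject_jitter_sd))
      rec <- generate_eeg(prof, n_channels = config$n_channels,
                          duration = config$duration_s, fs = config$fs,
                          seed = s, subject_id = cohort$subject_id[i],
                          group = as.character(cohort$group[i]), phase = ph)
      if (config$artifact_rate > 0)
        rec <- inject_artifacts(rec, config$artifact_rate,
                                config$artifact_amplitude, seed = s)$recording
      rec
    }
    manifest <- expand.grid(subject_id = cohort$subject_id, phase = phases,
                            stringsAsFactors = FALSE)
  } else {
    cohort <- read_cohort_csv(config$input$cohort_csv)
    manifest <- validate_inputs(config$input$eeg_paths, cohort, phases)
    n_sub <- nrow(cohort)
    get_rec <- function(i, ph) {
      path <- manifest$path[manifest$subject_id == cohort$subject_id[i] &
                              manifest$phase == ph]
      read_eeg_txt(path)
    }
  }

  # Per-subject, per-phase EEG features
  pe_subject <- matrix(NA_real_, n_sub, length(phases),
                       dimnames = list(cohort$subject_id, phases))
  wpli_subject <- array(NA_real_, c(n_sub, length(phases), 5),
                        dimnames = list(cohort$subject_id, phases,
                                        names(eeg_bands())))
  tfr_maint <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    for (ph in phases) {
      rec <- get_rec(i, ph)
      epochs <- tryCatch(
        preprocess(rec, config$f_low, config$f_high, config$reject_threshold,
                   config$target_fs),
        error = function(e) {
          note(sprintf("preprocess failed for %s/%s: %s",
                       cohort$subject_id[i], ph, conditionMessage(e)))
          NULL
        })
      if (is.null(epochs)) next
      ptc <- pe_timecourse(epochs, config$pe_m, config$pe_tau)
      pe_subject[i, ph] <- mean(ptc$global)
      wpli_subject[i, ph, ] <- band_profile(epochs,
                                            plv_threshold = config$plv_threshold)
      if (ph == "maintenance")
        tfr_maint[[i]] <- compute_tfr(rec, config$tfr_window, config$tfr_step,
                                      config$tfr_freqs)
    }
  }

  is_esk <- cohort$group == "esketamine"

  # PE group comparisons; FDR family = the anesthesia-timeline time-points.
  pe_tests <- lapply(phases, function(ph)
    compare_pe(pe_subject[is_esk, ph], pe_subject[!is_esk, ph], label = ph))
  p_fdr <- benjamini_hochberg(vapply(pe_tests, `[[`, numeric(1), "p_raw"),
                              family = "pe_timeline")
  for (k in seq_along(pe_tests)) pe_tests[[k]]$p_fdr <- p_fdr[k]
  names(pe_tests) <- phases

  # wPLI group comparisons; FDR family = the five bands within each phase.
  wpli_tests <- lapply(phases, function(ph) {
    tests <- lapply(names(eeg_bands()), function(b)
      compare_groups(wpli_subject[is_esk, ph, b], wpli_subject[!is_esk, ph, b]))
    p_fdr <- benjamini_hochberg(vapply(tests, `[[`, numeric(1), "p_raw"),
                                family = paste0("wpli_", ph))
    for (k in seq_along(tests)) tests[[k]]$p_fdr <- p_fdr[k]
    names(tests) <- names(eeg_bands())
    tests
  })
  names(wpli_tests) <- phases

  # Cluster-based permutation test on maintenance TFRs (esketamine - propofol).
  cluster <- tryCatch(
    permutation_test(tfr_maint[is_esk], tfr_maint[!is_esk],
                     n_perm = config$n_perm, seed = seeds[3]),
    error = function(e) {
      note(sprintf("cluster test failed: %s", conditionMessage(e)))
      NULL
    })

  tab1 <- table_one(cohort)
  state_contrasts <- list(
    baseline = compare_state_scores(cohort, "baseline_state"),
    month3 = compare_state_scores(cohort, "state_3mo"))

  # Adjusted outcome models + EEG-augmented logistic with LRT.
  logistic <- fit_logistic(cohort)
  if (isTRUE(logistic$separation)) note("logistic model: separation detected")
  linear <- fit_linear(cohort)
  eeg_cov <- data.frame(
    pe_maintenance = pe_subject[, "maintenance"] / 0.1,   # per 0.1 increase
    gamma_wpli_recovery = wpli_subject[, "recovery", "gamma"] / 0.1)
  augmented <- fit_logistic(cohort, extra_covariates = eeg_cov)
  lrt <- if (!is.null(augmented$coefficients) && !is.null(logistic$coefficients))
    likelihood_ratio(augmented, logistic) else NULL

  structure(list(
    config_summary = list(seed = config$seed, mode = config$input$mode,
                          n_channels = config$n_channels,
                          duration_s = config$duration_s, fs = config$fs,
                          n_perm = config$n_perm,
                          stage_seeds = as.integer(seeds)),
    cohort = cohort,
    manifest = manifest,
    features = list(pe = pe_subject, wpli = wpli_subject),
    pe = pe_tests,
    wpli = wpli_tests,
    cluster = cluster,
    table_one = tab1,
    state_contrasts = state_contrasts,
    models = list(logistic = logistic, linear = linear,
                  augmented = augmented, lrt = lrt),
    warnings = warnings),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  cohort: %d subjects (%s mode)\n", nrow(x$cohort),
              x$config_summary$mode))
  cat(sprintf("  PE maintenance: p = %.4g (p_FDR = %.4g)\n",
              x$pe$maintenance$p_raw, x$pe$maintenance$p_fdr))
  gam <- x$wpli$maintenance$gamma
  cat(sprintf("  gamma wPLI maintenance: p = %.4g (p_FDR = %.4g)\n",
              gam$p_raw, gam$p_fdr))
  if (!is.null(x$cluster))
    cat(sprintf("  cluster test: %d cluster(s)\n", length(x$cluster$clusters)))
  if (!is.null(x$models$lrt))
    cat(sprintf("  LRT (EEG covariates): chi2 = %.3f, p = %.4g\n",
                x$models$lrt$statistic, x$models$lrt$p_raw))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Full-precision machine-readable report (model objects and raw feature
#' arrays reduced to plain lists/tables). Byte-identical for identical
#' configs.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip_stat <- function(s) unclass(s)[c("test", "statistic", "p_raw", "p_fdr",
                                         "effect_size", "effect_name")]
  strip_model <- function(m) {
    if (is.null(m)) return(NULL)
    m <- unclass(m)
    m$model <- NULL
    m
  }
  out <- list(
    config = report$config_summary,
    cohort = as.data.frame(report$cohort),
    pe = lapply(report$pe, strip_stat),
    wpli = lapply(report$wpli, function(ph) lapply(ph, strip_stat)),
    cluster = if (!is.null(report$cluster)) summary(report$cluster),
    table_one = report$table_one,
    state_contrasts = lapply(report$state_contrasts, strip_stat),
    models = list(
      logistic = strip_model(report$models$logistic),
      linear = strip_model(report$models$linear),
      augmented = strip_model(report$models$augmented),
      lrt = if (!is.null(report$models$lrt)) strip_stat(report$models$lrt)),
    warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
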