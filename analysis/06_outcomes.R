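#!/usr/bin/env Rscript
# Step 6: confounder-adjusted outcome models -- logistic for 3-month
# improvement, linear for respiratory recovery time (both adjusting for age,
# etiology, baseline CRS-R) -- plus the exploratory EEG-augmented logistic
# model (maintenance PE and recovery gamma-band wPLI, per 0.1 increase) and
# its likelihood-ratio comparison against the confounder-only model.

source("analysis/common.R")

cohort <- load_cohort()
pe_tab <- read.csv(file.path(RESULTS_DIR, "pe_by_subject.csv"))
wpli_tab <- read.csv(file.path(RESULTS_DIR, "wpli_by_subject.csv"))

logit <- fit_logistic(cohort)
linear <- fit_linear(cohort)

idx <- match(cohort$subject_id, pe_tab$subject_id[pe_tab$phase == "maintenance"])
eeg_cov <- data.frame(
  pe_maintenance = pe_tab$pe[pe_tab$phase == "maintenance"][idx] / 0.1,
  gamma_wpli_recovery = wpli_tab$wpli[wpli_tab$phase == "recovery" &
                                        wpli_tab$band == "gamma"][idx] / 0.1)
augmented <- fit_logistic(cohort, extra_covariates = eeg_cov)
lrt <- likelihood_ratio(augmented, logit)

fmt <- function(fit, label) {
  cf <- fit$coefficients
  for (col in c("aor", "aor_low", "aor_high"))
    if (is.null(cf[[col]])) cf[[col]] <- NA_real_
  cf$model <- label
  cf
}
out <- rbind(fmt(logit, "logistic_improvement"),
             fmt(linear, "linear_recovery_time"),
             fmt(augmented, "logistic_improvement_eeg"))
write.csv(out, file.path(RESULTS_DIR, "models.csv"), row.names = FALSE)

cat("Adjusted logistic model, 3-month improvement:\n")
print(logit)
cat("\nAdjusted linear model, respiratory recovery time (min):\n")
print(linear)
cat("\nEEG-augmented logistic model:\n")
print(augmented)
cat(sprintf("\nLikelihood-ratio test (EEG covariates): chi2 = %.2f, df = %d, p = %.3g\n",
            lrt$statistic, lrt$df, lrt$p_raw))
grp <- logit$coefficients[logit$coefficients$term == "groupesketamine", ]
cat(sprintf("\nGroup effect: aOR = %.2f (95%% CI %.2f-%.2f) for esketamine;\n",
            grp$aor, grp$aor_low, grp$aor_high))
grp_l <- linear$coefficients[linear$coefficients$term == "groupesketamine", ]
cat(sprintf("recovery-time effect: %.2f min (95%% CI %.2f to %.2f).\n",
            grp_l$estimate, grp_l$ci_low, grp_l$ci_high))
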