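# Shared study configuration for the numbered analysis scripts.
# All scripts are run from the repository root:  Rscript analysis/01_simulate.R

suppressPackageStartupMessages(library(doceeg))

STUDY_SEED <- 42
N_PER_GROUP <- 17          # two-arm cohort, as in the study
N_CHANNELS <- 16           # reduced montage for desk-scale runtimes
DURATION_S <- 60           # one minute per phase recording
FS <- 250                  # analysis sampling rate
JITTER_SD <- 0.15          # per-subject lognormal spread of profile parameters
PHASES <- c("preoperative", "maintenance", "recovery")

RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

COHORT_CSV <- file.path(RESULTS_DIR, "cohort.csv")

load_cohort <- function() {
  if (!file.exists(COHORT_CSV))
    stop("run analysis/01_simulate.R first (missing ", COHORT_CSV, ")")
  read_cohort_csv(COHORT_CSV)
}

# Deterministic per-subject/phase seed matrix shared by every script.
subject_seeds <- function(n_subjects) {
  matrix(derive_seeds(STUDY_SEED + 1, n_subjects * length(PHASES)),
         nrow = n_subjects, dimnames = list(NULL, PHASES))
}

# Regenerate one subject's recording for a phase (bit-identical across
# scripts because profile jitter and signal share the same per-cell seed).
subject_recording <- function(cohort, i, phase) {
  profs <- default_profiles()
  prof0 <- switch(phase,
                  preoperative = profs$awake,
                  maintenance = if (cohort$group[i] == "esketamine")
                    profs$esketamine_maintenance else profs$propofol_maintenance,
                  recovery = profs$recovery)
  s <- subject_seeds(nrow(cohort))[i, phase]
  prof <- doceeg:::with_seed(s, doceeg:::jitter_profile(prof0, JITTER_SD))
  generate_eeg(prof, n_channels = N_CHANNELS, duration = DURATION_S, fs = FS,
               seed = s, subject_id = cohort$subject_id[i],
               group = as.character(cohort$group[i]), phase = phase)
}
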