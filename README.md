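# doceeg

Analysis pipeline for comparing two anesthetic regimes — an NMDA-antagonist
(esketamine) arm versus a GABAergic (propofol) arm — in patients with
disorders of consciousness (DoC), from multichannel intraoperative EEG and
3-month clinical follow-up. It is written for clinical neurophysiologists
and biostatisticians who need the full chain from raw multichannel signal to
confounder-adjusted outcome models in one tested, seeded, reproducible
package.

Because the patient recordings behind this design are not publicly
deposited, the package includes a first-class synthetic-data module that
generates EEG with controllable band power, lagged cross-channel coupling
and zero-lag volume-conduction mixing, plus clinical cohorts with a group
effect on improvement — so every stage runs and is tested without any
download.

## What it computes

**Permutation entropy (PE).** Each 2-s epoch and channel is embedded with
dimension *m* = 3, delay 1; each delay vector maps to the permutation
sorting it (ties broken by position). PE is the Shannon entropy of the
pattern frequencies, normalized by log *m*! to [0, 1]:

    H = -Σ p(π) log p(π) / log(m!)

**wPLI connectivity.** From Hanning-windowed Fourier coefficients of
2-s/50 %-overlap epochs, per channel pair and frequency bin:

    wPLI = |Σ_e Im S_xy(e)| / Σ_e |Im S_xy(e)|

band-averaged over delta (1–4), theta (4–8), alpha (8–13), beta (13–30) and
gamma (30–45 Hz), estimated only for pairs with phase-locking value
PLV > 0.1, and summarized as the mean over all channel pairs (a whole-brain
index per band). The imaginary cross-spectrum makes the index blind to
zero-lag volume conduction.

**Cluster-based permutation test.** Channel-averaged time–frequency power
maps (dB) are compared pointwise by pooled-variance t-tests; 4-connected
same-sign suprathreshold clusters (uncorrected p < 0.05) are scored by their
summed t and referred to a max-statistic null from random label permutations
(two-tailed, add-one p estimator).

**Clinical inference.** Shapiro–Wilk-routed two-sample tests with effect
sizes (Cohen's d, rank-biserial r, Cramér's V), Fisher's exact test,
Benjamini–Hochberg FDR within declared families, and adjusted logistic
(odds of 3-month improvement) and linear (respiratory recovery time) models
with a likelihood-ratio test of EEG-augmented fits.

## Worked example

```r
library(doceeg)

# one synthetic subject in the anesthetized (propofol-profile) state
rec <- generate_eeg(default_profiles()$propofol_maintenance,
                    n_channels = 16, duration = 60, fs = 250, seed = 1)
epochs <- preprocess(rec)          # 0.5-45 Hz, avg ref, 150 uV rejection, 2 s/50 %

mean(pe_timecourse(epochs)$global)
#> [1] 0.7738822

round(band_profile(epochs), 3)
#> delta theta alpha  beta gamma
#> 0.189 0.161 0.141 0.151 0.153

rec_awake <- generate_eeg(default_profiles()$awake, 16, 60, 250, seed = 1)
mean(pe_timecourse(preprocess(rec_awake))$global)
#> [1] 0.816114
round(band_profile(preprocess(rec_awake)), 3)
#> delta theta alpha  beta gamma
#> 0.168 0.153 0.170 0.198 0.246
```

The numbers show the two signatures the pipeline is built to detect: the
anesthetized profile has *lower broadband complexity* (channel-mean PE 0.774
vs 0.816 awake) and a *delta-led* connectivity hierarchy (0.189 at delta),
while the awake profile is *gamma-led* (0.246 at gamma). With 59 epochs the
independent-signal floor of the undebiased wPLI is ≈0.147, so whole-brain
values are read relative to that floor, not to zero.

The full study-scale analysis lives in `analysis/01_simulate.R` …
`analysis/06_outcomes.R` — numbered, self-narrating scripts that write their
tables under `results/analysis/`. From the seed-42 run: the maintenance-phase
PE comparison gives t = 7.68, p_FDR = 2.8e-08 (no pre/recovery difference);
the cluster test finds a positive high-frequency cluster (8–45 Hz, p_cluster
= 0.001) and a negative delta/theta cluster (1–6 Hz, p_cluster = 0.031); and
`06_outcomes.R` prints

```
Group effect: aOR = 1.91 (95% CI 0.41-8.86) for esketamine;
recovery-time effect: -4.43 min (95% CI -7.57 to -1.30).
```

(the odds ratio is noisy at n = 17 per arm — the acceptance script refits it
at n = 2000 per arm, where it recovers the generator's value).

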