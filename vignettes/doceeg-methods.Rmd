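---
title: "Methods: EEG complexity, connectivity and outcome analysis for anesthesia in disorders of consciousness"
author: "doceeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG complexity, connectivity and outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package analyzes

`doceeg` implements an end-to-end comparison of two anesthetic regimes in
patients with disorders of consciousness (DoC), combining three strands of
evidence:

1. **Brain-signal complexity** — normalized permutation entropy (PE) of the
   multichannel EEG, per 2-s epoch and channel, compared between arms at
   each phase of the anesthesia timeline (preoperative, maintenance,
   recovery).
2. **Functional connectivity** — the weighted phase lag index (wPLI) per
   canonical frequency band (delta 1–4, theta 4–8, alpha 8–13, beta 13–30,
   gamma 30–45 Hz), estimated from Hanning-windowed cross-spectra of
   2-s/50 %-overlap epochs, gated by the phase-locking value (PLV > 0.1) and
   averaged over all channel pairs into a whole-brain index per band.
3. **Clinical outcome** — a Coma Recovery Scale–Revised (CRS-R) based cohort
   table, a binary 3-month improvement outcome, and confounder-adjusted
   logistic and linear models, optionally augmented with the intraoperative
   EEG metrics and compared by likelihood-ratio test.

Group differences in time–frequency power are tested with a non-parametric
cluster-based permutation test (pointwise pooled-variance t-maps,
4-connected suprathreshold clusters scored by summed t, max-statistic null
from random label permutations).

Because the patient recordings behind this design are not publicly
deposited, the package ships a first-class synthetic-data module whose
defaults encode the study conditions; every analysis stage is exercised and
tested against it.

## Permutation entropy

A signal window is embedded with dimension `m` and delay `tau`; each delay
vector is mapped to the permutation that sorts it ascending, ties broken by
position (the earlier sample ranks lower). PE is the Shannon entropy of the
pattern frequencies, normalized by `log(m!)` to `[0, 1]`. The tie rule makes
the estimator total: a constant signal occupies the identity pattern only
and has PE exactly 0.

Defaults are `m = 3`, `tau = 1` at the 250 Hz analysis rate. The embedding
dimension is the anesthesia-EEG convention for minute-scale windows: `m = 3`
needs only `n >> m! = 6` patterns per 500-sample epoch, keeps the estimator
unbiased at 2-s epochs, and reproduces the `[0, 1]` working range reported
for this kind of data. Both parameters are exposed in the configuration.
PE is computed on the same 2-s/50 % epoch grid as the connectivity so both
metrics stay time-aligned, and reported per subject as the channel- and
epoch-mean.

## PLV-gated wPLI connectivity

For each epoch and channel the package stores one-sided Hanning-tapered
Fourier coefficients (2-s windows give 0.5 Hz bins). For a channel pair with
cross-spectrum \(S_{xy}\) per epoch:

- **PLV** is the modulus of the epoch-mean unit phasor of \(S_{xy}\),
  averaged over the band's bins — sensitive to any consistent phase
  relation, including zero-lag.
- **wPLI** is \(|\sum_e \mathrm{Im}\,S_{xy}| / \sum_e |\mathrm{Im}\,S_{xy}|\)
  per bin (0 where the denominator vanishes), band-averaged — blind to
  zero-lag (volume-conducted) coupling because instantaneous mixing leaves
  the cross-spectrum purely real.

Design choices worth knowing:

- The cross-spectral estimator is a single-Hanning-taper Welch scheme on the
  2-s/50 % grid. A multitaper hook exists conceptually but a single Hanning
  taper is what the stated window/overlap parameters pin down, so that is
  the implementation.
- The PLV gate is applied per pair per band (not per bin); gated pairs are
  set to 0 but stay in the whole-brain mean, so the denominator is the fixed
  pair count and the index is comparable across subjects. The wPLI values
  themselves are never thresholded or binarized.
- Band bins are half-open `[f_low, f_high)` so adjacent bands partition the
  frequency axis; gamma is capped at 45 Hz, inside the analysis passband.
- No debiasing term is applied. The undebiased estimator has a known
  finite-sample null floor, `E[wPLI] ≈ 2/sqrt(pi * n_epochs)` for
  independent signals — about 0.147 at the 59 epochs of a 60-s recording,
  dropping below 0.1 only beyond roughly 128 epochs. The test suite asserts
  this floor rather than pretending the null is 0; whole-brain indices from
  short recordings should be read relative to it. A numerical guard treats
  imaginary parts below `1e-12` of the cross-spectral modulus as exact
  zeros, so purely zero-lag mixtures report wPLI 0 instead of rounding
  noise.

## Cluster-based permutation test

Per subject the TFR is a channel-averaged sliding-window Hanning power map
in dB. The window length and step are not pinned down by the source design,
so the package documents its own defaults as assumptions: 1-s windows every
0.25 s on a 1–45 Hz grid. Pointwise pooled-variance t-tests
(`df = nA + nB − 2`) feed 4-connected same-sign clusters of pixels with
uncorrected `p < 0.05`; each cluster's mass is its summed t. The null is the
distribution of the maximum absolute cluster mass over label permutations
(both signs pooled — the two-tailed, strong-FWER variant), with the add-one
estimator `p = (1 + #{null ≥ |mass|})/(n_perm + 1)`, so p is never 0 and the
resolution floor is `1/(n_perm + 1)`. Permutations are drawn uniformly with
replacement from the label-assignment space, excluding the observed
labelling. 4-connectivity is the conservative adjacency default.

## Statistical routing and models

Continuous two-group comparisons pass a Shapiro–Wilk gate (`p ≥ 0.05` in
both groups routes to the pooled-variance Student t with Cohen's d, else
Mann–Whitney U with rank-biserial r). Pooled variance (not Welch) is used
deliberately: it is the form consistent with the reproducible baseline
CRS-R comparison this package treats as its exact numerical target.
Categorical variables use Fisher's exact test with Cramér's V from the
uncorrected chi-squared. FDR families are declared explicitly: PE across
the three timeline phases, and wPLI across the five bands within a phase,
each adjusted by Benjamini–Hochberg.

The outcome models adjust for age, etiology (TBI vs CVD) and baseline CRS-R.
Logistic CIs are Wald on the log-odds scale (matching the adjusted-odds-ratio
presentation convention); separation is detected and flagged rather than
silently reported. "Improved at 3 months" is defined as an upward transition
on the ordered ladder UWS < MCS− < MCS+ < EMCS, a definition the package
makes explicit because the binary outcome is otherwise underspecified; a
CRS-R point-change rule can be substituted in configuration. The ordinal
3-month group contrast (a t-test on the 0–3 ladder coding) is provided for
completeness but flagged as statistically crude — the adjusted logistic model
is the primary outcome analysis.

## The synthetic-data module

The generator is not a mock: it is the package's study-condition encoding,
and its defaults are fixed, not tuned per analysis.

**EEG.** Each state profile fixes relative band power weights, per-band
coupling (the fraction of band power carried by a shared oscillator), and a
1/f^k background slope. Per band, a shared band-limited Gaussian oscillator
is injected into every channel with a per-channel phase lag drawn as
`sign · U(pi/8, 3*pi/8)` — lags bounded away from 0 and pi, because wPLI is
blind to zero-lag coupling and a generator without explicit lags could not
produce controllable wPLI targets. Independent band-limited noise makes up
the rest of the band's power, so band power ratios track the weights
(verified within ×/÷1.5). Zero-lag volume conduction is a separate, explicit
mixing operation, and transient high-amplitude artifacts can be injected
with ground-truth event times for validating the rejection stage.

The four default profiles encode: a gamma-led awake state (coupling
hierarchy γ > β > α > θ > δ, gamma ≈ 0.5); delta-dominant anesthetized
states with suppressed gamma coupling (0.1 under the propofol profile, 0.2
under the esketamine profile, which also keeps about 2.8× more beta power);
and a delta-led recovery state with the inverted hierarchy
δ > θ > α > γ > β. Only orderings and ranges are targeted — the source
design reports its PE/wPLI levels descriptively, so exact values are not
meaningful targets. The default geometry is 64 channels, 60 s, 250 Hz;
250 Hz (not the acquisition rate of 1000 Hz) keeps runtimes proportionate,
and 1000 Hz is configuration-selectable. In cohort-level harnesses each
subject's profile parameters receive multiplicative lognormal jitter
(SD 0.15) — the generator's stand-in for inter-subject variability, chosen
as a realistic coefficient of variation for band-power ratios across
subjects.

**Cohort.** Continuous variables are Gaussian per arm (truncated where the
scale demands: CRS-R is an integer in 0–23, times are positive), because the
design only pins down means and SDs; no heavier-tailed model is attempted.
The binary improvement flag is drawn directly from a logistic model
(intercept, group effect log(6.84), and small age/etiology/CRS-R effects);
the intercept −2.61 places the propofol arm's improvement probability near
0.23 at covariate means, consistent with a large-but-borderline group
contrast at n = 17 per arm. Recovery time takes its covariate effects around
the pooled covariate means so that the *adjusted* group effect equals the
difference of the arm means (−5.4 min) exactly — the quantity the recovery
harness tests. The 3-month state moves up the ladder by one step (30 % of
the time two), capped at EMCS.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: no biophysical head model or
electrode-geometry-aware leakage (mixing is uniform), no non-stationarity
within a phase, no ocular/muscle artifact morphology (only amplitude
transients), no CRS-R item-level structure, and no correlation between a
subject's EEG features and their clinical covariates beyond the group
labels. Results on real recordings additionally depend on artifact handling
and montage details that the synthetic path holds fixed.

## Preprocessing contract

Fixed stage order: bandpass → average reference → amplitude-threshold epoch
rejection → downsample → 2-s/50 % epoching; the chain is deterministic and
re-runs bit-identically. The analysis passband default is 0.5–45 Hz — wide
enough for all five bands with margin, while removing drift and line
components; the acquisition-side 0.1–200 Hz band is a reader expectation
only. Filtering is frequency-domain with a flat unit-gain passband and
raised-cosine transitions centred on the requested edges (half-width
`min(edge/2, bandwidth/4, 2 Hz)`), applied by spectral multiplication:
zero-phase by construction (no phase distortion to bias PLV/wPLI), unit gain
at band centres, and attenuation beyond the transition that comfortably
exceeds a 20 dB/octave contract. Subspace-based artifact repair is *not*
implemented; the stand-in is absolute-amplitude epoch rejection at 150 µV
(configurable). The rationale: the downstream analyses only require clean
epochs, and threshold rejection is fully verifiable against the generator's
ground-truth artifact times, which a calibration-subspace method would not
be. Epochs are indexed by start time, half-open `[start, start + window)`.
Downsampling requires an integer rate ratio and anti-alias filters at 0.4×
the target rate.

## Numerical and degenerate-input choices

- PE tie-break is by occurrence order (stable), making constant signals
  well-defined; pattern counting is vectorized and tested against a
  brute-force enumerator.
- A two-sample t on zero pooled variance returns t = 0 only when the means
  agree; otherwise it is refused as degenerate rather than returning ±Inf.
- Mann–Whitney uses exact enumeration for `nA + nB ≤ 12` without ties,
  normal approximation with tie correction otherwise.
- Cluster p-values use the add-one estimator and never reach 0; an empty
  suprathreshold set yields an empty cluster list, not an error.
- Logistic separation (fitted probabilities at 0/1 or runaway coefficients)
  is flagged in the fit object; rank-deficient linear designs raise an error
  naming the collinear columns.
- All stochastic stages draw from named seeds expanded via one master seed
  (`derive_seeds`), so identical configurations give byte-identical reports.

## Problem sizes used by the shipped analyses and tests

The analysis scripts and test harnesses run the cohort at the study's
n = 17 per arm with 16-channel, 60-s, 250 Hz recordings — the package's
choice of a desk-scale montage that preserves every statistical property the
suite asserts (the whole-brain index is a mean over 120 pairs instead of
2016; orderings and group contrasts are unchanged). Cluster-test harnesses
use 200–500 permutations where the measured quantity is a rate, and the
full 1000 permutations in the shipped analysis script. Model-recovery
harnesses use n = 2000 per arm (point recovery) and 500 seeded cohorts of
n = 500 per arm (CI coverage).

## Known limitations

- The wPLI null floor means short recordings compress between-condition
  differences; compare conditions at matched epoch counts only.
- The per-pair-per-band PLV gate is one of two defensible readings of the
  gating rule (the other being per bin); the package implements the
  per-pair reading and exposes the threshold.
- Which discrete "time-points" constitute the PE FDR family is an
  approximation: the package compares phase-level summaries on the shared
  epoch grid.
- The FFT-domain filter assumes circular continuation at the segment
  boundaries; for minute-scale segments the boundary effect is negligible
  relative to the epoch rejection margin, but very short segments should be
  filtered with padding.
- Frequentist coverage of Wald logistic CIs degrades below roughly 50
  events per arm; the coverage harness runs at sizes where Wald is
  calibrated.
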