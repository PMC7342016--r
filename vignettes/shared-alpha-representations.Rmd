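---
title: "Decoding object representations shared between imagery and perception from oscillatory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding object representations shared between imagery and perception from oscillatory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alphashare)
```

## The analysis problem

When people visually imagine an object, the internal experience resembles
seeing it. If that resemblance has a neural basis, a classifier trained to
tell two objects apart from brain activity during *imagery* should also tell
them apart during *perception*, and vice versa. `alphashare` implements this
cross-task decoding logic for epoched EEG, restricted to induced (i.e.,
non-phase-locked) oscillatory power in discrete frequency bands, together
with the group statistics and the representational-similarity machinery
needed to say *where* (which band, which electrodes) and *in what format*
such shared representations live.

The pipeline has five stages, each an exported function family:

1. **Time-frequency decomposition** (`morlet_power`, `baseline_normalize`,
   `downsample_tf`, `band_vectors`): complex Morlet wavelets of constant
   600 ms length on 20 log-spaced bins between 5 and 31 Hz, computed per
   single trial and channel so that non-phase-locked power survives;
   absolute power (complex magnitude); per-trial dB normalization against
   the −500…−300 ms pre-stimulus baseline; averaging into 20 ms bins (50 Hz);
   aggregation into theta (5–7 Hz, 5 bins), alpha (8–13 Hz, 6 bins) and beta
   (14–31 Hz, 9 bins) response vectors with one value per electrode.
2. **Decoding** (`make_pseudotrials`, `cross_task_timegen`,
   `within_task_cv`, plus the `electrode_subset`, `peak_alpha_band`,
   `alpha_power_split` and `broadband_vectors` variants): pairwise linear
   C-SVC classifiers (libsvm, cost 1) on pseudo-trials (averages of random
   25% shares of a condition's trials), evaluated on every combination of a
   training time in one task and a testing time in the other. Both
   directions are averaged onto the same perception-time × imagery-time
   cell, and the whole procedure is repeated (default 100 times) with fresh
   pseudo-trial assignments.
3. **Localization** (`weights_to_pattern`, `pattern_topography`): classifier
   weights are not interpretable over sensors; multiplying them with the
   training-data covariance converts them into activation patterns whose
   magnitude can be ranked across electrodes.
4. **Representational similarity** (`neural_rdm_from_cluster`, `model_rdm`,
   `category_rdm`, `aggregate_vgg_rdms`, `auditory_model_rdms`,
   `compare_rdms`): the 12×12 matrix of pairwise cross-decoding accuracies,
   averaged over the cells of the significant cluster, is read as a neural
   representational dissimilarity matrix (higher accuracy = more dissimilar)
   and compared by Spearman rank correlation (66 lower-triangle entries)
   against model RDMs — visual DNN stages (19 layer RDMs aggregated into 8:
   convolutional blocks between pooling stages averaged, the three fully
   connected layers kept singly), a ±1 superordinate-category model, and
   auditory models (2 spectrotemporal stages, 11 auditory-DNN layers).
   Model feature matrices are consumed from files; the networks themselves
   are never executed here.
5. **Group statistics** (`sign_permutation_p`, `cluster_correct`,
   `fdr_correct`, `peak_latency_ci`): participant-level sign permutation
   (each participant's chance-centered map is flipped by an independent ±1;
   the identity permutation is included, so p ≥ 1/(n_perm+1)), cluster-size
   inference on the p < .05 supra-threshold cells (1-D adjacency for time
   courses, 8-connectivity for time–time maps), Bonferroni ×3 over bands for
   the cluster threshold, and Benjamini–Hochberg FDR across RDMs within a
   model family.

## The synthetic-data generator

Real recordings are not required anywhere: `sim_config` /
`simulate_cohort` generate multi-participant epochs with known ground
truth. Each trial is

* Gaussian 1/f^β background noise, synthesized in the frequency domain,
  independent per channel (β defaults to 1), unit RMS;
* a spatially broad 10 Hz background with uniformly random phase per trial
  and participant-specific channel loadings (amplitude 0.5 by default) —
  ongoing alpha that carries no object information;
* an object-specific burst: carrier drawn per trial from a truncated normal
  peaked at the center of `shared_band` (sd = bandwidth/8), uniformly random
  phase per trial (so trial averaging cancels it — *induced* power), an
  envelope that is nonzero only inside the task's latency window, and a
  channel loading given by the participant's unit-norm object pattern on a
  posterior channel subset. The same pattern drives both tasks: that is
  the operational meaning of a "shared representation" here.

Defaults encode the study conditions: 63-channel montage (10-10 layout,
35 anterior / 37 posterior electrodes with the central and temporal rows in
both halves), 12 objects, 1000 Hz sampling, perception epochs −600…1100 ms
and imagery epochs −600…3100 ms, signal windows 50–750 ms (perception) and
600–2300 ms (imagery).

Three generator choices deserve explanation:

* **Carrier distribution.** Alpha peak frequencies cluster near 10 Hz; a
  uniform draw over 8–13 Hz would put substantial carrier mass within one
  wavelet bandwidth of the nearest theta-band bin (7.34 Hz), making theta
  decoding genuinely above chance for a purely spectral reason. The
  truncated normal keeps the planted energy where the band label says it is.
* **Envelope.** The burst envelope uses Hann ramps of 250 ms by default and
  a perception signal window of 50–750 ms. Shorter, sharper bursts (e.g., a
  400 ms window with 50 ms ramps) are nearly rectangular; their spectral
  sidelobes carry ~20% amplitude at ±4 Hz, i.e. real object-specific energy
  inside the beta band, and the beta null then fails for a reason that has
  nothing to do with the decoder. The long smooth burst keeps planted power
  band-limited, which is the envelope's entire purpose.
* **snr.** The paper-style analysis gives no usable effect size, so the
  default (0.7, the per-channel amplitude ratio of burst to background on
  carrier channels) was calibrated once so that the documented recovery
  suite passes at the documented cohort size (10 participants), and is
  recorded in `sim_config()`. At this level alpha in-window decoding sits
  near 80–90% for single participants — comfortably away from both chance
  and the regime where spectral leakage becomes detectable.

What the generator does **not** emulate: biophysical volume conduction
(channels are statistically, not anatomically, coupled), eye/muscle
artifacts, evoked components beyond the optional `phase_locked` flag,
between-participant alpha-frequency variability (available via
`shared_band`, used in the individual-alpha tests), and temporal dispersion
of single-trial imagery onsets. Passing recovery tests therefore shows the
*analysis code* recovers planted structure under realistic spectra — not
that the paper's biological claims are reproduced.

## Numerical conventions

* "Constant 600 ms wavelet length" is implemented as a fixed support with
  the Gaussian envelope truncated at ±300 ms = 3σ (σ_t = 100 ms at every
  frequency, so spectral bandwidth σ_f ≈ 1.6 Hz at all bins).
* "Absolute power" is the complex magnitude √(re² + im²); dB is
  10·log10(power/baseline mean). A trial whose value equals its baseline
  mean maps to 0 dB.
* Downsampling bins are left-closed/right-open, anchored at stimulus onset;
  timestamps are bin starts; incomplete edge bins are dropped.
* Bin-to-band assignment rounds each bin center to the nearest integer Hz
  and tests membership in the nominal integer ranges — the only simple rule
  that reproduces the 5/6/9 split of the canonical grid.
* Pseudo-trial remainders (trials not divisible by 4) are dropped at random
  per repeat. Within-task cross-validation rotates the held-out pseudo-trial
  over all 4 folds per repeat (variance reduction; one more documented
  choice on top of the repeat averaging).
* Each of the 2×4 test pseudo-trials is scored individually; a cell's
  accuracy is the fraction correct of 8.
* The SVM sees the dB features as they are (no further standardization);
  the classifier's positive decision value corresponds to the first
  training class by libsvm's ordering, which `train_pair_classifier` pins
  down by construction.
* Sign permutations include the identity; tests on accuracies and RSA
  correlations are right-tailed (the hypotheses are directional); cluster
  statistic is size (cell count), contiguity 8-connected in 2-D;
  the activation-pattern covariance is the pooled class-mean-removed
  estimator with 1/(n−1); peak-latency confidence intervals use a seeded
  percentile bootstrap over participants (the CI method is not dictated by
  the analysis design — a documented assumption).
* In `peak_alpha_band` ties are broken toward the lowest candidate
  frequency; the 1 Hz-resolution decomposition reuses the same Morlet
  operator on an integer 7–14 Hz grid.
* The alpha enhancement/suppression split computes each trial's mean
  baseline-normalized alpha power over the full 0–800 ms perception window
  (the post-stimulus statistic window is otherwise unspecified) and
  subsamples the larger class at random.
* Spearman comparisons use the 66 lower-triangle entries and average ranks
  on ties (which matters for the ±1 category model).

## Problem sizes used by the shipped tests and analysis scripts

The package defaults are the full-scale parameters (63 channels, 40 trials
per object and task, 100 decoding repeats, 10,000 permutations, 20 ms
decoding grid). The test suite and the `analysis/` drivers run a desk-scale
demonstration chosen as the smallest cohort that still recovers every
planted contrast: 10 participants, 16 channels (8 anterior-only + 8
posterior-only montage sites), 6 objects (15 pairs; 12 objects and all 66
pairs for the RSA stage), 12 trials per object and task, 250 Hz simulation,
decoding grids of 100 ms (perception) × 200 ms (imagery), 20 repeats, 1,000
permutations. Familywise-error calibration of the cluster test runs on 200
synthetic null cohorts at the statistics level (participant × map Gaussian
samples), where the error rate of the machinery — not the EEG physics — is
what is being measured.

## Known limitations

* Cross-decoding accuracy maps from a single cohort have strongly
  correlated cells (pseudo-trial partitions and trials are shared across
  cells), so the permutation null allows large clusters; at 10 participants
  only effects covering a sizable map fraction reach significance.
* Magnitude (not squared) power plus dB normalization makes the per-bin
  information profile peak slightly off the true carrier frequency when a
  strong same-frequency background is present — visible in
  `peak_alpha_band` if the unspecific alpha background dwarfs the signal.
* The HDF5 epoch container stores one task per file; vendor EEG formats are
  out of scope (convert externally and write the container with
  `write_epochs`).
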