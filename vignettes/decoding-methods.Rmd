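---
title: "Decoding imagined 3D arm movements from EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding imagined 3D arm movements from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtpbci` implements a complete motion-trajectory-prediction (MTP)
brain-computer interface for imagined three-dimensional arm movements, from
raw multichannel EEG to closed-loop feedback simulation, together with a
filter-bank common-spatial-patterns (FBCSP) multi-class comparator. This
vignette is the package's own account of the science: the models, their
assumptions, the tunable parameters and the choices we made where the
design was genuinely open.

## The experimental protocol

Two virtual arms move from per-arm home positions toward three targets each,
placed at the same orthogonal distance along the horizontal (X), vertical
(Y) and depth (Z) axes (`target_layout()`). A calibration (offline) session
comprises six runs; each run is a 10 s initialisation followed by six 28 s
blocks, one per arm-by-target combination in seeded random order. A block is
a 4 s voice cue plus two 12 s sub-blocks, each a
move-pause-return-pause cycle (4 + 2 + 4 + 2 s). Only the first sub-block
displays the movement; the second is pure kinesthetic imagery, and only its
data enter decoder training, so that visual movement observation cannot leak
into the features. A run therefore lasts exactly 178 s and the six-run
offline part, with 40 s rests after every run, 21.8 minutes (usually quoted
rounded to 22). The online protocol allows up to 7 s per movement with a
2 s hold, 4 s pause structure, capping a block at 30 s and a run at 190 s
(23 minutes for six runs including rests).

The ideal movement speed ramps linearly from zero until half the
home-target distance is covered and then stays constant until arrival.
Solving the two phase areas fixes the ramp at two thirds of the epoch and
the peak speed at `1.5 * distance / duration`; this is the simplest profile
consistent with the protocol description and it integrates in closed form,
which the tests exploit (`velocity_template()`).

## The velocity decoder

Movement information is carried by the *band power* of sensorimotor
rhythms: mu (8-12 Hz), low beta (12-18 Hz), high beta (18-28 Hz) and low
gamma (28-40 Hz). The pipeline is:

1. **Channel QC** (`qc_channels()`): amplitude and flatness thresholds as an
   automated surrogate for manual inspection.
2. **Common average reference** (`car_filter()`): subtract the
   instantaneous mean over channels, removing common-mode artifacts.
3. **Zero-phase FIR filter bank** (`bandpass_filterbank()`), then **sliding
   window band power** (`band_power()`): mean squared amplitude in 250 ms
   windows stepped by one sample (8.33 ms) during calibration or 25 ms (the
   40 Hz display rate) for prediction.
4. **Standardization** (`standardize()`): each band-by-channel series is
   divided by its standard deviation, estimated on *training folds only*
   and reused verbatim on test folds. The printed form of the
   standardization is scale-only; because the surrounding text could also be
   read as prescribing a temporal difference before scaling, a
   `difference = TRUE` switch is provided but off by default.
5. **Lag embedding** (`lag_embed()`): features at `t, t - d, ..., t - L*d`
   are concatenated (embedding dimension L + 1). The investigated grid is
   d in {50, 100, 200} ms and L in {1, 2, 4, 8}.

The decoder itself (`train_mlr()`) is ordinary least squares, one
regression per spatial axis and per arm (six independent regressions):

    v_i[t] = a_i + sum_{n,f,k} b_{infk} S_{nf}[t - k] + e_i[t]

Least squares is solved by QR; a 1e-8 ridge on the normal matrix is the
fallback for rank-deficient designs (for example all-zero features). This
ridge is a numerical guard, not a regularizer: whenever the design has full
rank the solution is the exact OLS optimum, which the tests verify against
a dense coefficient grid.

Predictions are smoothed with a 9-sample (200 ms) centered moving average.
For trajectory metrics both predicted and target velocities are normalized
to unit length per sample, converted to *relative coordinates* - the running
mean of the normalized velocities within a trial, zero-referenced at the
trial start - and compared by the mean 3D distance (`reconstruction_error()`).
The running-mean form is used for all model selection; a conventional
cumulative-sum integration is available for display only
(`relative_coordinates(mode = "integrate")`), never for selection. Under the
running-mean form a perfectly decoded straight trial sits at its target's
unit direction vector, which is why those unit vectors serve as the
classification landmarks.

### Architecture search

`recursive_selection()` searches channels and lag parameters under 6-fold
leave-one-run-out cross-validation (folds = runs, sub-block-2 data only).
At each step every lag-grid cell is cross-validated, channels are scored by
`R_nf = sum_k sum_i b^2 / (L + 1)` averaged over folds and bands
(`score_channels()`), and the lowest-scoring channel is eliminated (ties
drop the higher montage index, for determinism). The search repeats until
the floor is reached, and the architecture with minimal mean reconstruction
error among channel-set sizes 6-12 is selected, independently per arm. The
grid is re-run in full at every elimination step; at the package's desk
scale one step costs seconds, so nothing is reused across steps.

### Closed-loop feedback

`simulate_online_session()` replays the online paradigm at 40 Hz. The
displayed velocity blends the normalized target direction and the decoder's
normalized prediction, `rho * v_target + (1 - rho) * v_pred` with
`rho = a / 100`; the assisted schedule starts at 50% and drops 6% per run to
20% (`assistance_schedule()`), and direct feedback uses 0%. Blending
operates on normalized vectors exactly as printed; speed is a separate
scalar. The displayed speed constant is not stated anywhere we could find,
so the simulator scales it such that a perfect decoder traverses
home-to-target in the 4 s offline-template time. Position integrates the
blended velocity, is clamped to the workspace box (the unclamped predicted
coordinates are logged separately), and a movement epoch ends early once the
hand is within 20% of the movement distance from its destination
(`cue_mute_check()`), followed by a 2 s hold, relocation to the endpoint
and a 4 s pause.

### Evaluation

`time_varying_da()` classifies the predicted relative coordinate at every
within-trial sample to the nearest landmark; a sample succeeds when it is
strictly closer to the actual target than to both non-targets, with ties
counted as failures (conservative and deterministic). Trials are truncated
to their common length and pooled. The label-independence null is built by
permuting target labels over whole trajectories (`permutation_null()`),
keeping each trial's three coordinates together. Analytically the null is
100/3 % for three balanced classes and 50% for two; the acceptance suite
recovers both from simulation. Comparisons use the two-sided Wilcoxon test
(`rank_test()`), exact for n <= 25 without ties. The per-sample permutation
p-values and the peak-window rank test are both reported; how the original
study aggregated its significance window is not stated, so neither is
asserted as canonical.

## The FBCSP comparator

The comparator classifies trials (not trajectories) with one-vs-rest
two-class machines, one per class: per band (six bands, 0.5-4 through
28-40 Hz), CSP filters from the generalized eigendecomposition of the
trace-normalized class covariance against the composite covariance
(`csp_fit()`); time-varying log-variance features in 1 s windows stepped by
200 ms covering -4 s to +12 s around movement onset (`logvar_features()`,
76 window positions); feature selection by mutual information on an
equal-frequency-quantized feature space (`mi_select()`); and a regularized
LDA with covariance shrinkage toward the scaled identity (`rlda_fit()`).
Multi-class decisions take the argmax of the one-vs-rest signed distances.

Parameter selection runs inside a nested cross-validation (`nested_cv()`):
outer folds match runs (single-session; 6 outer / 5 inner) or sessions
(multi-session; 7 outer / 6 inner); the inner leave-one-out level picks the
CSP pair count {1, 2, 3}, quantization levels {4, 8, 16}, selected feature
count {4, 8, 16} and shrinkage {0, 0.1, 0.3, 0.5, 0.9} maximizing peak
inner accuracy. The ranges are package choices (the source method optimized
them without publishing ranges); the shrinkage grid replaces the original
toolbox's automatic analytic choice. Equal-frequency (rank-based)
quantization was chosen over equal-width because it is invariant to feature
scale. Trial covariances are trace-normalized before averaging - standard
CSP conditioning. After common-average referencing the composite covariance
is singular in the channel-mean direction; a small shrinkage ridge restores
invertibility and parks that direction mid-spectrum, where it is never
selected.

Contribution maps (`contribution_maps()`) average MI weights per band and
window offset (the time-frequency heat map) and, at the peak-accuracy
offset, aggregate the MI-weighted magnitudes of the forward-model CSP
*patterns* (columns of the inverse filter matrix) per channel. Patterns -
not filters - express where a component projects on the scalp; using filter
coefficients instead would highlight noise-suppression channels. Magnitudes
are aggregated, making the maps invariant to the sign indeterminacy of CSP.

## The synthetic-data generator

No public recordings accompany the protocol, so `synthesize_mtp_session()`
and `synthesize_class_session()` generate sessions with known ground truth;
they are first-class, tested code, and every decoding claim in the test
suite is made against them.

For the velocity decoder the generator plants, on designated channels, a
band-limited carrier whose amplitude is `sqrt(c0 + g * v(t - delta))`, so
that *power* - the decoder's feature - is exactly affine in the lagged
velocity; the linear model is correctly specified by construction, which is
what makes parameter-recovery tests meaningful. Carrier frequencies (10,
14, 22, 34 Hz) are chosen so that every carrier, pairwise sum/difference
frequency and second harmonic completes an integer number of cycles inside
the 250 ms power window at 120 Hz, and carriers sharing a band get
quarter-turn phase offsets: all interference terms then average to zero
exactly, including the cross terms that common-average referencing
introduces between channels. Defaults: encoding lag 100 ms (inside the lag
grid), gain 2 (units/s)^-1, baseline power 1 uV^2, encodings on
C3/FC3/CP3 and C4/FC4/CP4 - the contralateral sensorimotor channels. On
top sit per-channel 1/f background noise (spectrally shaped white noise,
exponent 1), a common-mode 1/f component added to all channels specifically
to exercise the CAR stage, and 50 Hz line noise. The default noise scales
(0.3 uV channel, 0.5 uV common mode, 0.2 uV line against unit-power
carriers) give a clearly decodable but not trivial session.

For the classifier fixture, designated channels carry band-limited rhythms
whose variance is multiplied by a class factor during that class's task
epochs; the default halves C4 mu variance during left-arm imagery and C3 mu
during right-arm imagery - synthetic event-related desynchronization with a
2x between-class variance ratio.

What the generator does *not* emulate: volume conduction from cortical
sources (no leadfield), ocular/muscular artifacts, non-stationary baselines
across runs, or inter-subject variability. Passing tests therefore show
that the algorithms are implemented correctly and recover planted structure
at realistic SNR - not that real EEG yields the original study's accuracy
figures, which depended on recordings that were never deposited and are
explicitly out of scope here.

## Numerical choices and degenerate inputs

* FIR filters are windowed (Blackman) linear-phase designs with >60 dB
  single-pass stop-band attenuation, applied forward-backward via FFT
  convolution, so the effective response is magnitude-squared with exactly
  zero phase. Transition widths are 1 Hz, narrowed to the band edge near
  low frequencies, so that the four-band power sum of broadband noise loses
  only a few percent of the nominal 8-40 Hz spectral mass at the band
  crossovers. Filter edge transients decay within a fraction of a
  second; protocol sessions begin with a 10 s initialisation and end with a
  40 s rest, which keeps task epochs clear of the recording boundaries.
* 8.33 ms is interpreted as exactly one sample at 120 Hz and 25 ms as
  exactly three samples.
* Windows and epochs are half-open `[t, t + w)`; timestamps are seconds
  from session start; sample indices are 1-based in R code, 0-based in all
  written tables.
* Zero-norm velocity vectors normalize to the zero vector and are flagged,
  not errors: the first sample of every ideal trial has zero speed.
* A zero-variance feature (flat channel) is an error at standardization,
  pointing at QC; a zero-variance log-variance window is floored at
  `1e-12` of the signal scale.
* All-zero paired differences in the rank test return p = 1 with a warning
  (identical samples carry no evidence), matching the exact-test
  convention.
* Random draws always flow through explicit integer seeds; the pipeline
  refuses to run without one and records every derived stage seed in its
  manifest.

## Problem sizes

The package's reference analyses run at desk scale: six-run synthetic
sessions (about 21 minutes of 16-channel EEG at 120 Hz each), decoder
recovery and permutation tests on one session per seed across ten seeds,
and classifier fixtures of 36-72 trials per class built from one or more
such sessions. The architecture-search examples start from 8-channel
subsets with reduced lag grids; the full 16-channel, 12-cell grid search is
available through the same interface and simply costs proportionally more.

## Known limitations

* The EEG container is a delimited table (`write_session()`); EDF is not
  read or written.
* The decoder assumes the band-power-to-velocity map is linear and
  stationary within a session; the generator satisfies this by
  construction, real data need not.
* `crossvalidate()` expects the canonical six-run session; other run counts
  require an explicit override and the Box-style trial bookkeeping then
  adapts accordingly.
* The closed-loop simulator is a faithful replay of the control law and
  paradigm timing, not a model of subject adaptation: it cannot reproduce
  feedback-induced strategy changes discussed in the closed-loop BCI
  literature.
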