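# mtpbci

Motion trajectory prediction (MTP) brain-computer interfacing in R:
decoding imagined three-dimensional arm movements from the band power of
sensorimotor EEG rhythms, with a closed-loop feedback simulator and a
filter-bank common spatial patterns (FBCSP) multi-class comparator.

## Who this is for

BCI researchers and students who want a complete, tested, desk-scale
reference implementation of a continuous kinematics decoder — the kind of
pipeline usually scattered across lab-internal Matlab/Simulink code — in
idiomatic R, exercised end-to-end on synthetic EEG with known ground truth.

## The science in brief

Two virtual arms move from home positions toward three orthogonal targets
per arm. Imagined movement velocity is decoded from standardized EEG band
power (mu 8–12, low beta 12–18, high beta 18–28, low gamma 28–40 Hz) with a
lag-embedded multiple linear regression, one model per axis and arm:

v_ij[t] = a_ij + Σ_n Σ_f Σ_k b_ijnfk · S_jnf[t−k] + ε_ij[t]

where S_jnf[t] = B_jnf[t]/σ_Bjnf is band power standardized by its
training-fold standard deviation. Channels and lag parameters are chosen by
recursive channel elimination (scores R_jn = Σ_k Σ_i b²_ijnfk/(L+1),
averaged over folds and bands) under 6-fold leave-one-run-out
cross-validation, with trajectory quality measured as the mean 3D distance
ε_t between target and reconstructed relative coordinates (running mean of
per-sample-normalized velocities). Closed-loop feedback blends normalized
target and predicted directions, v* = ρ·v*_target + (1−ρ)·v*_pred with
ρ = a/100 and an assistance schedule falling from 50% to 20% in 6% steps.
Decoding accuracy is the per-sample percentage of trials whose predicted
coordinates lie nearest their own target landmark, compared against a
whole-trajectory label-permutation null and Wilcoxon rank tests. The FBCSP
comparator classifies trials via per-band CSP filters, sliding-window
log-variance features, quantized mutual-information selection and
regularized LDA inside a nested (inner–outer) cross-validation.

Because no recordings were published for this protocol, the package ships a
synthetic-session generator whose band-power features are affine in the
lagged target velocity by construction (and whose class fixtures emulate
contralateral mu desynchronization), so every stage can be validated
against planted structure. See `vignette("decoding-methods")` for the full
account.

## Worked example

```r
library(mtpbci)

layout <- target_layout()
sched  <- build_offline_schedule(layout, n_runs = 6, seed = 7)
sess   <- synthesize_mtp_session(sched, layout, encoding_spec(),
                                 noise_spec(1, 0.3, 0.5, 0.2), seed = 12)

bp <- session_band_power(sess$recording, feature_step = 0.025)
cv <- crossvalidate(bp, sess$kinematics, sched, arms = "left")
cv
#> <mtp_cv> 6 folds, 36 trials, mean eps: left=0.451

ftr <- forward_trials(cv, "left")
pn  <- permutation_null(ftr$trials, ftr$labels,
                        landmark_directions(layout, "left"),
                        n_perm = 200, seed = 1)
pn$observed
#> <da_curve> 18 trials, 160 samples, peak DA 100.0% at 1.10 s
round(pn$null_mean[pn$observed$peak_index], 1)
#> [1] 32.1
```

Reading: the decoder, trained per fold on the imagery-only sub-blocks of
five runs, reconstructs the held-out run's trajectories with a mean
relative-coordinate error of 0.45 (in units of the normalized velocity
frame; an uninformative decoder sits near 1.0); from about 1.1 s after
movement onset every forward trial is classified to the correct target
(DA 100%), while label permutation stays at the 33.3% three-class chance
level. A full orchestration — synthesis, preprocessing, architecture
search, cross-validation, closed-loop replay, evaluation — is
`run_pipeline(pipeline_config(seed = 1))`, and a thin command-line wrapper
lives at `inst/scripts/mtp-pipeline.R`.

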