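# nirsconn

Analysis pipeline for **guided circle-drawing coordination experiments
recorded with multichannel fNIRS**: a subject traces a displayed circle with
one or both index fingers (unilateral clockwise/counterclockwise movements,
bilateral in-phase and anti-phase combinations) while cortical hemodynamics
are recorded over prefrontal, motor and occipital regions. The package is
aimed at motor-control and neurorehabilitation researchers who want the full
chain — kinematics, signal cleaning, activation mapping, connectivity,
statistics — as tested, reusable functions rather than ad-hoc scripts.

## What it computes

**Kinematics.** Trials are converted to polar coordinates about the guide
center; performance is summarized by four divisor-*n* RMS metrics:

- SDR = sqrt(Σ(rᵢ − r̄)²/n) — radius variability
- RE = sqrt(Σ(rᵢ − r₀)²/n) — radius error against the guide radius r₀
- SDAV = sqrt(Σ(wᵢ − w̄)²/n) — angular-velocity variability
- AVE = sqrt(Σ(wᵢ − w₀)²/n) — angular-velocity error against the guide w₀

with the exact identity RE² = SDR² + (r̄ − r₀)².

**Preprocessing.** Modified Beer–Lambert conversion of optical densities to
Δhbo/Δhbr (30 mm separation, configurable DPF, standard extinction table);
moving-SD motion-artifact detection with cubic-spline repair; zero-phase
Butterworth band-pass 0.021–0.6 Hz plus band-stop 0.08–0.12 Hz (cardiac and
Mayer-wave suppression), run as second-order sections.

**Activation.** Per-channel GLM on canonical double-gamma HRF regressors
(OLS, t statistics), and the model-free task-minus-rest trapezoidal integral
of Δhbo per block.

**Connectivity & graphs.** Analytic Morlet CWT (ω₀ = 6) phase extraction on
a log-spaced grid in the LF (0.021–0.145 Hz) or HF (0.145–0.6 Hz) band;
phase-locking value PLV = |n⁻¹ Σ exp(i(φˣ − φʸ))| per pair, averaged over
the band; binarization at the largest threshold that keeps the network
connected (maximum-spanning-tree bottleneck); clustering coefficient,
global/node/node-local efficiency, degree, and small-world σ against
degree-preserving rewired nulls, aggregated to regions.

**Statistics.** Type-II factorial ANOVA, paired t tests, Benjamini–Hochberg
FDR, Pearson correlation — each returning tidy report rows.

**Synthetic cohorts.** A seeded generator emulating the block design
(21 subjects × 8 conditions, 12 s task / 15 s rest, 28.5 Hz trajectories,
11 Hz × 30-channel fNIRS) with injected radius bias, activation amplitudes,
pairwise LF phase coupling, physiological oscillations and artifacts — the
ground truth every stage is validated against.

## Worked example

```r
library(nirsconn)

design <- cohort_design(n_subjects = 1, n_blocks_per_condition = 4, seed = 7)

# a subject with a 0.1-unit radius bias and contralateral motor activation
traj <- gen_trajectory(trajectory_ground_truth(radius_bias = 0.1,
                                               radius_noise_sd = 0.05),
                       duration = 12, rate = 28.5, seed = 7)
kinematic_metrics(traj)
#>    hand condition trial        sdr       re         sdav          ave   n
#> 1 right      RHCW     1 0.04989052 0.114678 1.658379e-14 1.658969e-14 342

regions <- default_channel_regions()
amp <- ifelse(regions == "RMC", 1, 0)     # right motor cortex active
rec <- gen_nirs_recording(design, nirs_ground_truth(activation_amplitude = amp,
                                                    noise_sd = 0.5),
                          seed = 7, conditions = "LHCW")
clean <- preprocess_nirs(rec)
clean$events <- rec$events
fit <- fit_glm(clean, build_design(rec$events, rec$t))
head(fit$table[order(fit$table$p), c("channel", "region", "beta", "t")], 3)
#>    channel region      beta        t
#> 19    ch19    RMC 0.9390100 45.41006
#> 17    ch17    RMC 0.9221854 43.25166
#> 20    ch20    RMC 0.8613413 38.57564

net <- threshold_connected(connectivity_matrix(
  cwt_phase(concat_task(rec, "LHCW"), band_spec("HF", n_freqs = 10))))
ms <- network_metric_set(net, n_null = 20, seed = 7)
round(ms$global, 3)
#>      global_efficiency clustering_coefficient      small_world_sigma
#>                  0.567                  0.437                  1.617
```

The kinematic row says the drawn circle wobbles by ~0.05 units (SDR) and
sits ~0.11 units off the guide radius (RE ≈ sqrt(bias² + noise²)); the GLM
table ranks the injected right-motor channels first with amplitudes near
the injected 1.0; the network block binarizes the HF-band PLV matrix at
its connectivity bottleneck (τ* = 0.455 here) and reports moderate
efficiency and clustering with σ > 1 against rewired nulls. (The LF band
needs ≥ 4 cycles of 0.021 Hz, i.e. ≥ ~190 s of concatenated task signal —
16+ blocks — which is why this short demo uses HF.)
`run_pipeline(pipeline_config())` chains all stages on a synthetic cohort
and writes every artifact family (CSV/TSV + JSON manifest) to a run
directory.

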