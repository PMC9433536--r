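---
title: "Methods: kinematics, activation and phase-locking connectivity for circle-drawing fNIRS experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, activation and phase-locking connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsconn)
```

## The experiment this package models

`nirsconn` analyzes guided circle-drawing coordination experiments: a subject
traces a displayed circle with one or both index fingers on a tablet
(unilateral clockwise/counterclockwise movements, and bilateral in-phase (IP)
or anti-phase (AP) combinations) while cortical hemodynamics are recorded with
multichannel fNIRS over six regions (left/right prefrontal cortex, motor
cortex and occipital lobe). The canonical design is 21 subjects, 8 movement
conditions, ~12 s of movement per trial with 15 s rests, trajectories sampled
at 28.5 Hz, and 30 fNIRS channels at 11 Hz.

The package implements four analysis layers — kinematics, preprocessing,
activation, connectivity/graph metrics — and the group statistics linking
them, plus a synthetic-data generator that emulates the design with known
ground truth so that every stage can be validated without access to any real
recording.

## Kinematic metrics

Each trial is converted to polar coordinates about the known guide-circle
center: radius $r_i$, unwrapped angle $\theta_i$, and angular velocity $w_i$
by finite differences (central in the interior, one-sided at the ends, so the
velocity series has full length). Four root-mean-square metrics summarize a
trial, all in the population (divisor-$n$) form:

$$\mathrm{SDR} = \sqrt{\tfrac{1}{n}\sum_i (r_i - \bar r)^2}, \qquad
  \mathrm{RE} = \sqrt{\tfrac{1}{n}\sum_i (r_i - r_o)^2},$$
$$\mathrm{SDAV} = \sqrt{\tfrac{1}{n}\sum_i (w_i - \bar w)^2}, \qquad
  \mathrm{AVE} = \sqrt{\tfrac{1}{n}\sum_i (w_i - w_o)^2},$$

where $r_o$ and $w_o$ are the displayed guide radius and (signed) angular
velocity. SDR/SDAV measure within-trial variability, RE/AVE accuracy against
the guide. The divisor-$n$ convention gives the exact identity
$\mathrm{RE}^2 = \mathrm{SDR}^2 + (\bar r - r_o)^2$, which the test suite
asserts to $10^{-12}$.

Design choices here that the task description leaves open:

* the guide center and parameters are taken from the known task display, not
  fitted per trial; a least-squares circle fit (`to_polar(center = "fit")`)
  is available for exploratory use;
* acquisition transients from mode switching are removed by trimming a
  configurable window (default 0.5 s) at each end of a trial
  (`trim_trace()`), since no exact removal rule is defined by the task;
* metrics are computed per trial and then averaged per condition downstream
  (pooling is a caller-side choice); units are the input tablet units.

## fNIRS preprocessing

**Modified Beer–Lambert conversion.** For optical recordings at wavelengths
$\lambda \in \{740, 808, 850\}$ nm, concentration changes solve, per sample
and channel, the least-squares system over wavelengths

$$\Delta OD(\lambda) = d \cdot \mathrm{DPF}(\lambda)\,
  \big(\varepsilon_{HbO}(\lambda)\, \Delta hbo +
       \varepsilon_{HbR}(\lambda)\, \Delta hbr\big),$$

with source–detector distance $d = 30$ mm and a configurable differential
pathlength factor (default 6.0 at all wavelengths, a standard adult-head
value; the acquisition description does not state one). Extinction
coefficients come from the standard Gratzer/Kollias compilation tabulated in
`extinction_coefficients()`; concentrations are reported in µmol/L.

**Motion artifacts.** A sample is flagged when the sample standard deviation
over a centered 10-sample moving window strictly exceeds a threshold
(default 5, in the concentration units of the data). The printed unit of that
threshold in the source protocol (mmol/L) is physiologically implausible for
concentration changes, so the package treats it as a configurable dial rather
than a physical constant. Flagged runs are merged, padded by ±0.5 s, and
repaired with a cubic spline fit on up to 10 clean samples on each side;
segments touching a record boundary fall back to nearest-value extension.
Repair is idempotent and leaves clean samples untouched bit-for-bit.

**Filtering.** A 0.021–0.6 Hz band-pass and a 0.08–0.12 Hz band-stop, both
zero-phase (forward–backward). The band-pass is realized as a cascade of
4th-order Butterworth high-pass and low-pass filters rather than a single
8th-order band-pass transfer function: at 11 Hz sampling the lower edge is
0.004 of Nyquist and a direct high-order recursion is numerically fragile.
Each filter additionally runs as a cascade of second-order sections (biquads
obtained from the pole pairs), which keeps forward–backward filtering linear
to ~$10^{-12}$ instead of ~$10^{-8}$. Measured on 11 Hz probes, the chain
passes 0.05 Hz within 1%, and attenuates 1 Hz (cardiac) and 0.10 Hz (Mayer
waves) by more than 20 dB.

One caveat is inherited from the protocol itself: respiratory interference
(~0.2–0.3 Hz) lies *inside* the 0.021–0.6 Hz pass band, so it is not removed
by these filters; the band definitions are kept as printed and the residual
is documented rather than silently fixed.

## Activation: GLM and task-minus-rest integral

The design matrix contains one regressor per condition — the task boxcar
convolved with a canonical double-gamma HRF (response gamma peaking at 6 s,
undershoot gamma at 16 s scaled by 1/6, unit peak) — plus an intercept and a
single linear drift. The same HRF is used by the synthetic generator, making
amplitude recovery a well-posed calibration: noiseless recovery is exact to
machine precision and, at SNR 1, estimated amplitudes fall within ±3
standard errors of truth in ≥99% of simulations.

Fitting is ordinary least squares per channel with two-sided t tests on the
residual degrees of freedom. No autoregressive prewhitening is applied; with
structured physiological noise OLS standard errors are anti-conservative at
the single-subject level, which is why group inference (across subjects, with
FDR over channels) is the supported inference level. This is a known
limitation, not an accident.

Activation intensity is additionally quantified without a model: the
trapezoidal integral of Δhbo over each task window minus the
duration-matched integral over the immediately preceding rest window,
averaged over blocks of a condition. The rest baseline is anchored to the end
of the preceding rest period; blocks with less than 5 s of preceding rest are
skipped with a warning.

## Connectivity: Morlet phase and PLV

Instantaneous phase is extracted with an analytic Morlet continuous wavelet
transform ($\omega_0 = 6$, the standard time–frequency compromise;
configurable) on a log-spaced grid of 20 frequencies (default) inside a band.
Two bands are predefined: HF 0.145–0.6 Hz and LF 0.021–0.145 Hz; network
analysis defaults to LF, where slow myogenic/neurogenic activity lives.
Samples inside the cone of influence (e-folding time $\sqrt 2 \cdot$ scale)
are excluded per frequency, and records must cover at least 4 cycles of the
lowest band frequency.

The phase-locking value of channels $x, y$ is the modulus of the mean unit
phasor of their phase difference,
$\mathrm{PLV} = |\,n^{-1}\sum_t e^{i(\phi_{xt} - \phi_{yt})}|$, computed per
grid frequency and averaged (unweighted by default; amplitude-weighted
behind a flag) across the band. For independent phases PLV decays as
$\tfrac{\sqrt\pi}{2} n^{-1/2}$, which the tests verify against a Rayleigh
Monte-Carlo oracle.

The weighted PLV network is binarized at the *connectivity bottleneck*: the
largest threshold $\tau^\*$ that keeps the graph connected, which equals the
minimum edge weight on the maximum spanning tree (ties at $\tau^\*$ are all
kept). This is the literal reading of thresholding "under the condition of
ensuring the connectivity of the brain network"; a fixed-density sweep was
considered and rejected as the default because no density value is specified
anywhere in the protocol. PLV is computed on the task-concatenated series of
a condition group (rest removed) by default; trial-wise analysis is possible
by slicing recordings before calling the connectivity stage.

## Graph metrics

On the binarized adjacency: clustering coefficient (mean over nodes of the
fraction of connected neighbor pairs; 0 for degree < 2), global efficiency
(mean inverse shortest-path length over ordered pairs), node efficiency,
node-local efficiency (global efficiency of the neighbor-induced subgraph),
and degree. All are authored in-package and verified to $10^{-12}$ against
brute-force Floyd–Warshall / triangle-enumeration oracles on every connected
graph with ≤6 nodes (via the graph atlas) and on random 8-node graphs,
including the exact identity that global efficiency equals the mean node
efficiency on connected graphs.

"Small-world properties" are summarized as
$\sigma = (C/C_{rand})/(L/L_{rand})$ with null means over 100
degree-preserving Maslov–Sneppen rewired connected graphs (seeded;
igraph's rewiring is used as standard machinery). On complete graphs
rewiring is the identity, so $\sigma = 1$ exactly; on Erdős–Rényi-like
graphs $\sigma \approx 1$; on ring lattices with shortcuts $\sigma > 1$.
Channel-level metrics are averaged to regions by unweighted mean — the
region-collapsed-graph alternative was rejected because channels, not
regions, are the stated network nodes.

## Group statistics

Factorial ANOVA (two-way for unilateral handedness × orientation, three-way
with condition for bilateral analyses) uses Type II sums of squares, the
main-effect-focused default for possibly unbalanced designs; noiseless
degenerate designs get explicit conventions (p = 0 for a nonzero effect over
zero residual, p = 1 for a zero effect). Paired t tests compare IP vs AP
network metrics across subjects; Benjamini–Hochberg FDR is applied across the
30 channels within a condition; Pearson correlations link activation and
network metrics to kinematics. Correlation analyses pool subject × condition
observations, as the canonical design implies (n ≈ 84–168 points); note that
pooling treats repeated measures of a subject as independent and therefore
inflates n — a subject-mean analysis is the conservative alternative.

## The synthetic generator

`gen_nirs_recording()` builds each channel as

* activation amplitude × (block boxcar ⊛ canonical HRF), per condition;
* a narrowband low-frequency oscillation (carrier 0.05 Hz — inside the LF
  band, outside the Mayer notch — with a diffusing random phase, innovation
  scale 0.6 rad/√s) whose inter-channel coupling is controlled by convex
  signal mixing: channel $k$ receives the shared carrier with weight
  $\sqrt{\kappa_k}$ and an independent carrier with weight
  $\sqrt{1-\kappa_k}$, so a block-uniform coupling matrix with value
  $\kappa$ gives each within-block pair a shared power fraction $\kappa$.
  $\kappa = 1$ forces PLV = 1; $\kappa = 0$ leaves the floor set by record
  length, and the measured PLV is monotone in $\kappa$ (verified over
  100-seed Monte Carlo). Arbitrary non-block pairwise targets are
  approximated, not matched exactly;
* cardiac (1 Hz), respiratory (0.25 Hz) and Mayer (0.1 Hz) sinusoids with
  random phases, white Gaussian noise, and optional spike/step motion
  artifacts at a configurable events/minute rate;
* Δhbr as a damped inverted copy (−0.3×) of the task response with its own
  noise.

`gen_cohort()` jitters per-subject parameters around per-condition effect
specifications (Gaussian subject random effects, default SD 10% of the
effect) and emits a ground-truth table for recovery tests. All randomness
derives from one master seed; identical seeds give bit-identical cohorts.

What the generator does *not* emulate: photon transport and optode-scalp
coupling, serially correlated (1/f) instrument noise, eye/EMG artifacts,
habituation or learning across blocks, and hemispheric asymmetries beyond
what an effect specification injects. Passing tests therefore demonstrate
the correctness and calibration of the *analysis machinery* under the stated
noise model, not the physiological validity of any real-data conclusion.

Inter-subject variability parameters are placeholders chosen for plausible
effect-to-noise ratios, since no population estimates are available in the
source description.

## Problem sizes used in validation

The test-and-acceptance workload uses Monte-Carlo sizes chosen to make the
checked properties sharp while keeping a full run on one CPU comfortable:
1000 random traces for the kinematic oracles; 100 concentration pairs for
the Beer–Lambert round trip; 200 seeds at n = 10⁴ for the Rayleigh PLV
check; 100 seeds per coupling level (20-block records) for monotonicity;
100 random 8-node graphs plus the complete ≤6-node atlas for graph oracles;
500 simulations for GLM calibration; 1000 for ANOVA calibration; and 50,
200 and 30 cohorts of 21 subjects for the three end-to-end mirrors
(contralateral confinement, activation-kinematics correlation, IP-vs-AP
coupling contrast). The IP/AP contrast injects RPFC coupling 0.85 vs 0.25
against a 0.1 background — a strong but within-range contrast chosen once as
the generator's study condition.

## Known limitations

* No AR prewhitening in the GLM (single-subject inference is
  anti-conservative under colored noise; use group-level tests).
* The respiratory band is inside the printed pass band (see above).
* The bottleneck threshold retains exactly the maximum-spanning-tree
  backbone plus ties; on near-uniform PLV matrices the binarized graph can
  be dense.
* Pairwise coupling targets outside block-uniform structures are only
  approximated by the shared-carrier mixing construction.
* SNIRF/HDF5 I/O is not provided; recordings use the documented CSV + JSON
  dialect (`write_recording()` / `read_recording()`).
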