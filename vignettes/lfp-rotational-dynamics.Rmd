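---
title: "Rotational low-frequency LFP dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational low-frequency LFP dynamics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdyn)
```

## The scientific problem

During isometric wrist control, cursor movements decompose into discrete
submovements that recur rhythmically at roughly 3 Hz. Low-pass-filtered,
mean-referenced local field potentials (LFPs) recorded from motor cortex
oscillate at the same frequency, with a phase that differs systematically
across electrodes. Projecting the multichannel LFP onto its first two
principal components (LFP-PCs) therefore yields a planar trajectory that
rotates once per submovement, in a fixed direction. `lfpdyn` packages the
analyses that quantify this structure:

1. **Trajectory geometry.** The areal velocity
   $\nu(t) = \tfrac12\, x(t) \times \dot{x}(t)$ measures the area swept per
   unit time about the origin; for a circular orbit of radius $r$ at
   frequency $f$, $|\nu| = \tfrac12 r^2\, 2\pi f$. Its magnitude tracks
   submovement speed, and in 3D PC space the orientation of the
   areal-velocity vector (the rotation axis) tilts with submovement
   direction.
2. **Kinematic decoding.** The per-submovement window-averaged 3D areal
   velocity $v_i$ is modeled as $v_i = s_i\, b(\theta_i)$ with the Fourier
   direction basis
   $b(\theta) = b_0 + b_1\cos\theta + b_2\sin\theta + b_3\cos 2\theta +
   b_4\sin 2\theta$ (15 free scalars, fit by linear least squares; no
   harmonics beyond $2\theta$ to avoid overfitting). Held-out speed is
   decoded as $|v_j|/|b_0|$ and direction by a grid argmax of
   $v_j \cdot b(\theta)/|b(\theta)|$. Performance is scored by
   $\mathrm{CoD}_{\text{speed}} = 1 - \sum_j (s_j-\hat s_j)^2 / \sum_j s_j^2$
   (note: normalized by the raw sum of squares, so decoding everything as
   zero scores exactly 0) and
   $\mathrm{CoD}_{\text{dir}} = \tfrac1N\sum_j \cos(\theta_j - \hat\theta_j)$
   (chance 0; uniform random directions give a 90° expected absolute
   error).
3. **Linear dynamics.** The planar trajectory is summarized by
   $\dot{x} = A x$ with $\mathrm{tr}(A) = 0$ (three free parameters; the
   off-diagonals are *not* forced to be antisymmetric, because projections
   of other conditions onto the task PC axes need not be orthogonal).
   Fits are scored by the vector CoD
   $1 - \int |\hat{\dot x} - \dot x|^2 dt / \int |\dot x|^2 dt$ over the
   entire recording. With the trace constraint the eigenvalues are
   $\pm\sqrt{-\det A}$; when $\det A > 0$ the model oscillates at
   $\sqrt{\det A}/2\pi$ Hz.
4. **Phase structure.** Event-relative per-channel phases come from the
   Hilbert transform of event-triggered averages (phase 0 at a cosine
   peak); cross-state consistency is tested with the
   Jammalamadaka–SenGupta circular-circular correlation; spike phase
   locking with the Rayleigh test, after rotating the PC plane so the
   submovement-triggered trajectory has zero phase at peak speed.

## What the synthetic generator emulates

No public recording accompanies this problem, so every analysis is
validated end-to-end on `simulateTaskSession()` /
`simulateSedationSession()`, which emulate the statistical structure of
such sessions with known ground truth:

- a latent planar oscillator at `oscillatorFreq` (3 Hz) whose amplitude
  envelope bursts around each submovement, mixed into channels with a
  fixed phase $\psi_c$ and gain per channel;
- submovements from a *phase-locked renewal process*: each oscillator
  cycle emits at most one event (probability `submovementRate /
  oscillatorFreq`), so inter-event intervals peak at multiples of the
  ~333 ms cycle, matching the observed rhythmicity; peak speeds are
  log-normal (median 60 %/s, log-SD 0.4, truncated at 35 %/s so all true
  events exceed the 30 %/s detection threshold) and peak cursor speed is
  locked to a fixed oscillator phase;
- the window-averaged planar areal velocity of the noise-free latent
  equals `peakSpeed / speedCoupling` exactly, and a third latent dimension
  receives direction-dependent loading $\tan(\texttt{directionTilt})
  \cos(\phi - \theta_i)$, tilting the rotation axis by `directionTilt`
  (default 15°) in an azimuth set by the movement direction;
- spikes are inhomogeneous Poisson with rate
  $\propto \exp(\kappa \cos(\phi - \phi_{\text{pref}}))$, optionally
  modulated by the amplitude envelope; EMG is rectified noise modulated by
  the speed envelope;
- the sedation mode adds >250 µV K complexes (difference-of-Gaussians
  transients) at cycle-snapped Poisson times with refractory spacing,
  flanked by 1–3-cycle delta bursts that reuse the *same* $\psi_c$ pattern
  at `sedationAmplitudeRatio` (10×) the task amplitude, with spiking
  concentrated on the rising phase — so cross-state phase-consistency and
  model-generalization analyses have a known positive control.

Background noise is pink (1/f, 7 µV) plus white (5 µV), with a common
single-phase 20 Hz beta component (3 µV): pure white noise would make the
delta band unrealistically weak, and the single-phase beta reproduces the
empirical finding that beta-band projections lack rotational structure, so
the trace-zero model should fail there.

What the generator does **not** emulate: biophysical mechanisms (it is
phenomenological), electrode drift and artifacts, non-stationary behavior,
spindles, or realistic spike waveforms (spike times only). Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical structure, not performance on real recordings.

## Numerical and design choices

- **Filtering.** "Delta" is a pure 5 Hz low-pass (four-pole Butterworth),
  not a band-pass with a high-pass edge; "beta" is a 10–30 Hz band-pass
  (order-2 design = 4 poles). Both are applied forward and backward
  (zero phase, squared magnitude response) with odd-reflection padding of
  ten cutoff periods, long enough for the edge transient to decay below
  1e-9. Recordings shorter than three cutoff periods are refused. The IIR
  inner loop is compiled (direct-form-II-transposed) because the
  white-noise null filters ~6 × 10^9 samples.
- **Derivatives** are central differences (one-sided at the ends); at
  488 samples/s and 3 Hz the sinc attenuation is 2.5 × 10⁻⁴, far below
  every tolerance used.
- **PCA** is computed over the full recording (the generator has no
  intertrial structure worth excluding) via the channel covariance. Two
  sign conventions make results reproducible: each component's
  largest-magnitude loading is positive, and PC2 is negated if the mean
  planar areal velocity is clockwise, so predominant task rotation is
  anticlockwise. Other conditions are always projected onto the task basis
  (including its channel means).
- **Detection.** Submovements: strict local maxima of radial speed above
  30 %/s with a 100 ms refractory rule (larger peak wins) — below the
  300 ms cycle, so rhythmic events are never merged; direction is the
  angle of the instantaneous torque velocity at the peak. K complexes:
  local maxima above 250 µV with 1 s spacing. The decoder and the
  trajectory averages anchor on the time of peak speed.
- **Interval autocorrelation** normalizes the pairwise within-trial
  interval histogram by the analytic expectation for the observed event
  counts placed uniformly in the same trial windows (triangular window
  correction, n(n−1)/2 pairs per trial), so a Poisson process is flat at 1.
- **Decoder.** The direction argmax uses a 0.5° brute-force grid (exact
  enough, reproducible; ties take the smallest angle). Leave-one-out fits
  use downdated normal equations (a 5 × 5 solve per event). Events whose
  held-out fit or decode fails are excluded from the CoDs and counted,
  never imputed. Shuffle significance permutes only the speed (or
  direction) labels across submovements, leaving the areal-velocity
  vectors fixed; thresholds are the 95th percentiles over (by default)
  1,000 surrogate data sets.
- **Dynamics.** The trace-zero least-squares problem is solved in closed
  form from the 3 × 3 normal equations. CoD integrals are Riemann sums
  over all samples, no trial gating. The white-noise null uses 10 channels
  × 10 min × 488 samples/s × 200 replicates (a typical session shape;
  configurable) — enough that the 95th percentile stabilizes near 10⁻³
  while one replicate stays near one second of compute.
  Cross-correlation frequency takes the peak–trough interval of the
  PC1×PC2 cross-correlation nearest zero lag (parabolic sub-sample
  refinement) as half a period, and errors when the extrema fall below an
  amplitude floor of 3/√n.
- **Circular statistics** follow the standard toolbox formulas: the
  Jammalamadaka–SenGupta coefficient with its asymptotic normal p value
  (undefined — an error — when either sample has zero circular resultant,
  which is why the generator's default channel phases span 3/4 of the
  circle rather than all of it), and the Rayleigh approximation
  $p = \exp(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n))$.
- **Spike phases** default to the polar angle of the (rotated) PC pair;
  a Hilbert-phase variant is provided. Samples with orbit radius below 5%
  of the maximum are masked, and a unit errors out if more than half its
  spikes fall on masked samples.
- **Spectra** use rectangular 2,048-point segments without overlap
  (0.238 Hz resolution at 488 samples/s) for both coherence and power;
  the coherence attribute `confidenceFloor` gives the
  $1 - 0.05^{1/(L-1)}$ zero-coherence threshold. Per-segment means are
  removed to keep low-frequency leakage out of the first bins.
- **Serialization** uses a plain-text session directory (CSV arrays +
  YAML metadata) written at full double precision (`%.17g`), so
  write→read round trips are bit-identical and containers remain
  readable without this package.

## Scales used by the shipped tests

The test suite exercises everything on desk-scale synthetic sessions:
120 s task/sedation pairs (≈300 submovements, ≈14 K complexes), a 120 s
noise-free sparse session for exactness checks, 200-replicate Monte Carlo
loops for calibration claims (Rayleigh level, Poisson flatness of the
interval autocorrelation), 200-shuffle significance runs, and the
10-channel × 10-min × 200-replicate white-noise null. These sizes were
chosen so each statistical check has comfortable power while the whole
suite runs in minutes on one core.

## Known limitations

- The generator's submovement kinematics are out-and-back radial pulses;
  real center-out trajectories include holds, corrections and
  direction-dependent speed profiles.
- Amplitude SNR of awake LFP is a free parameter (the literature gives
  only an order-of-magnitude statement relative to sedation); defaults put
  the task-mode delta orbit near 55 µV against ~9 µV of in-band noise.
- The trace-zero model is fit by ordinary least squares; measurement noise
  in the PCs attenuates $A$ slightly (≈4% at default SNR), which is
  visible as a small downward bias of the recovered model frequency. This
  mirrors how the estimator behaves on real data and is left uncorrected.
- `correlationFrequency()` assumes a single dominant oscillation; with
  broadband or multi-peaked spectra the nearest peak–trough pair may not
  be meaningful (the amplitude floor guards the worst cases).
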