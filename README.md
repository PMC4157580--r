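# lfpdyn

Analysis of rotational low-frequency dynamics in multichannel motor-cortical
local field potentials (LFPs) and their coupling to movement kinematics.

During isometric cursor control, movements decompose into submovements that
recur rhythmically at ~3 Hz, and low-pass-filtered, mean-referenced LFPs
oscillate at the same frequency with electrode-specific phases. Projected
onto their first principal components (LFP-PCs), the multichannel LFP traces
out a planar trajectory that rotates once per submovement. `lfpdyn` is for
researchers who want to quantify that structure — in recordings or in
simulation — with a tested, reusable pipeline:

- **Preprocessing**: zero-phase four-pole Butterworth filtering into delta
  (5 Hz low-pass) and beta (10–30 Hz) bands, within-area mean referencing,
  PCA with an anticlockwise orientation convention, and projection of any
  condition onto task-derived axes.
- **Event detection**: submovements as radial-speed peaks > 30 %/s,
  K complexes as surface-LFP deflections > 250 µV, and a Poisson-normalized
  interval-autocorrelation histogram for rhythmicity.
- **Trajectory geometry**: areal velocity ν(t) = ½ x(t) × ẋ(t) (for a circle
  of radius r at frequency f, |ν| = ½ r² · 2πf), rotation frequency
  f(t) = |ν| / (π|x|²), and event-aligned averages in nine speed groups and
  six direction bins.
- **Kinematic decoding**: the Fourier-parameterized model
  v_i = s_i · b(θ_i), b(θ) = b0 + b1 cos θ + b2 sin θ + b3 cos 2θ +
  b4 sin 2θ (15 coefficients, linear least squares), leave-one-out decoding
  of speed (|v_j|/|b0|) and direction (grid argmax of the normalized dot
  product), CoD metrics and 1,000-fold shuffle significance.
- **Linear dynamics**: the trace-zero model ẋ = A x (3 free parameters),
  the vector coefficient of determination, cross-condition generalization,
  a white-noise null calibration of the fit, and the cross-correlation
  frequency of the PC pair.
- **Phase statistics**: Hilbert event-relative phases, circular-circular
  correlation, Rayleigh tests of spike phase locking in a plane rotated to
  zero phase at peak speed, Welch coherence and power spectra with
  2,048-point rectangular windows.
- **Synthetic sessions**: `simulateTaskSession()` and
  `simulateSedationSession()` generate task and sedation recordings with
  known ground truth (latent oscillator, injected submovements and
  K complexes, phase-locked spikes, mixing matrix), so every stage is
  testable end to end without animal data.

## Worked example

```r
library(lfpdyn)
report <- runPipeline(list(seed = 1, simulation = list(duration = 120),
                           nShuffles = 200, nullReps = 50, nullDuration = 120))
print(report)
```

Output (abridged) from the run above:

```
  detect:
    nSubmovements                295
    intervalModeMs               337.5
  decode:
    codSpeed                     0.992
    codDirection                 0.9574
    shuffleThresholdSpeed        0.7941
    shuffleThresholdDirection    0.08026
  dynamics:
    codFit                       0.9387
    modelFrequencyHz             2.877
    codFitBeta                   0.001213
    codGeneralization            0.9596
    nullP95                      0.01033
  phase:
    rhoCC                        0.9998
    nUnitsPhaseLocked            15
    meanPreferredPhase           -0.6342
    coherencePeakHz              3.098
```

Reading this: the 120 s simulated task session contains 295 submovements
whose interval histogram peaks at ~337 ms (the ~3 Hz rhythm). Leave-one-out
decoding of submovement speed and direction from LFP-PC areal velocities is
near-perfect on synthetic coupling (CoD 0.99 / 0.96), far above the
shuffle 95th percentiles. The trace-zero dynamics model fits the delta-band
trajectory (CoD 0.94) at 2.88 Hz, fails on the single-phase beta band
(CoD ≈ 0.001), and generalizes from task to sedation (CoD 0.96). The
white-noise null (here 50 reps of 2 min for speed) calibrates chance for
that fit at ~0.01; per-channel submovement phases correlate almost
perfectly with K-complex phases (ρ_CC ≈ 1), all 15 units are significantly
phase-locked, and their mean preferred phase (−0.63 rad) precedes peak
speed. Speed–LFP coherence peaks at the 3 Hz oscillator bin.

`vignettes/lfp-rotational-dynamics.Rmd` documents the models, estimator
conventions and generator design in detail.

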