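---
title: "Methods: synthetic seismo-acoustic scenes and CNN-based rumble monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic seismo-acoustic scenes and CNN-based rumble monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`rumbleR` implements a complete, desk-scale analysis chain for monitoring
low-frequency elephant vocalizations (rumbles) with a co-located
three-component seismometer and an infrasound sensor, both sampled at
200 Hz. Because no field recordings ship with the package, every stage is
exercised against a synthetic scene generator with exact ground truth: the
generator defines the study conditions, and the tests measure whether the
analysis recovers what was injected.

The chain is: scene synthesis → band-pass and spectrogram preprocessing →
fixed-size snippet images → CNN rumble/noise classification (within-domain,
cross-domain, and combined protocols) → continuous-record scanning →
event-catalog temporal analytics → particle-motion polarization.

## The synthetic scene model

### Rumbles

A rumble is modeled as a tonal call with a fundamental frequency contour
$f(t) = f_a\,(1 - d\,(1 - w(t)))$ over the call duration $T$, where the
weight $w(t)$ rises as a half-sine from 0 to 1 over the first quarter of
the call, holds a plateau at 1 over the central half, and falls over the
last quarter: the contour sweeps up from $f_a(1-d)$ at the edges to its
apex $f_a$ and dwells there. The plateau is deliberate — it is the only
stationary region of the contour, so the call's spectral energy
concentrates at a single well-defined apex frequency. Smooth sweeps with a
momentary apex (raised-cosine or half-sine weights) were tried and
rejected: chirp leakage can put the band-power maximum one or two bins away
from the apex for deep contours, which breaks apex recovery from
spectrogram ridges. `n_harmonics` integer harmonics ride on the same phase
track with amplitudes decaying geometrically (`harmonic_decay` per order,
default 0.55, so the fundamental is the strongest line and the second
harmonic is faint — matching the observation that the second harmonic is
rarely prominent). Cosine on/off ramps over 10% of the duration keep
onsets smooth.

Default priors reflect the observed call population: apex 10–25 Hz,
duration 1–8 s, peak ground velocity 1–10 µm/s. Infrasound peak pressures
are not reported numerically for the observed population; the prior
(0.1–1 Pa) was set once so that night-time SNR is comparable across
domains. The same waveform is radiated into both domains; on the seismic
side it is partitioned across N/E/Z by per-call direction cosines drawn
uniformly on the sphere, so the peak *vector* ground velocity equals the
spec's peak while the component split is random (the analysis averages
component spectrograms, so the split is unobservable downstream — except to
the polarization module, which gets its own purpose-built generator,
`synth_rumble_polarized()`, with a vertically polarized fundamental and a
transverse-horizontal harmonic).

Scheduled calls keep a default minimum onset separation of 12 s (one
analysis window), so injected calls are resolvable at the 12-s scale;
explicit onset lists can place calls arbitrarily close when rapid sequences
are the object of study.

### Footfalls

Locomotion transients are exponentially damped, high-passed Gaussian noise
bursts (0.05–0.3 s), rendered on the seismic channels only — the channel
contract that gives seismic data its unique value. The pulse shape is a
modeling choice; only "sharp, broadband, seismic-only" is treated as a
constraint.

### Background noise

Both channels carry Gaussian broadband noise at a night RMS (seismic
0.1 µm/s, infrasound 0.01 Pa), multiplied during opening hours
(07:00–17:00 UTC, hard step) by a day factor: 7 for seismic (within the
observed 5–10 range), 1.5 for infrasound (the pressure sensor is much less
affected by daytime activity). Daytime seismic noise additionally carries
monochromatic machine lines at 12, 25 and 30 Hz and Poisson-scheduled
broadband bursts (20/h). The line RMS (0.15 µm/s each) was derived
analytically before any testing: it is large enough that a fine-resolution
(0.25-Hz) spectrum shows the lines ≥ 10 dB above neighbouring bins, yet
small enough that the lines perturb the band-limited day/night RMS ratio by
under 10%, so the day factor remains recoverable from hourly noise
profiles.

## Preprocessing

All analysis operates on 1–80 Hz band-passed data, filtered zero-phase
(forward-backward) by a cascade of a 4th-order Butterworth high-pass and an
8th-order low-pass. The steeper upper section is needed because the 80-Hz
corner sits near the 100-Hz Nyquist frequency: with a 4-pole upper edge,
enough transition-band energy survives one pass that a second pass still
removes ~1.5% RMS, whereas the cascade makes filtering idempotent to under
1% — so downstream statistics do not depend on how often a trace happened
to pass through the filter. Spectrograms are
Hann-windowed STFTs with a 1-s window and 75% overlap by default — 1 Hz
resolution resolves 10–25 Hz fundamentals and the 0.25-s hop resolves 1-s
calls. The scaling is a one-sided PSD calibrated so that total map energy
matches signal energy (Parseval), which the tests verify to 1%. Seismic
N/E/Z component maps are averaged cell-wise on the linear power scale
before any downstream use.

Classifier inputs are 12-s snippets with the pick at the temporal centre,
rendered as 232 × 115 × 3 images: dB scale, dynamic range clipped to the
2nd/98th percentile *per snippet* (this normalizes out the large day/night
level differences so the network must learn spectral shape, not level), a
fixed perceptually-uniform colour table, bilinear resampling to the fixed
pixel grid. The published pixel dimensions are taken at face value; no
physical dpi metadata is honoured. Edge picks whose window would leave the
record are rejected rather than padded.

## The classifier

The network is the fixed architecture: three convolutional blocks (2 ×
conv-32@5×5, 2 × conv-64@3×3, 2 × conv-128@5×5), each followed by 2×2
max-pooling and 25% dropout; a dense 128-unit ReLU layer with 40% dropout;
a 2-class softmax. Convolutions use "same" padding so three poolings fit
the 115-pixel height (115 → 57 → 28 → 14); with the 232-pixel width this
gives 51,968 flattened features and 7,350,434 trainable parameters, which
the tests check against a closed-form count. Training uses RMSprop
(learning rate 5e-4, ε = 1e-8, decay 0.9), batch size 8, sparse categorical
cross-entropy, a stratified 70/10/20 split, and at most 30 epochs.

"Early stopping" is interpreted as: hard cap at 30 epochs, validation-loss
patience of 3 with best-weight restoration, plus a convergence stop once
validation accuracy reaches 1 and validation loss falls below 0.05 —
on separable synthetic sets there is nothing left to learn at that point,
and a longer patience would only spend further single-CPU epochs
confirming it before restoring the same best weights.

There is no deep-learning framework in the package's dependency set; the
network is implemented directly in C++ (RcppArmadillo over BLAS GEMM via
im2col, single-threaded), with a float32 training path and a double
path used by the numerical gradient check in the test suite. All
randomness — initialization, shuffling, dropout — derives from one
integer-seeded Mersenne Twister stream, making training bit-reproducible
on one machine; this is what the pipeline determinism test asserts.

Training sets are synthesized as 12-s mini-scenes: call snippets place one
prior-drawn rumble over background noise with its centre jittered uniformly
by ±2 s — sliding-window scanning presents calls up to half a hop
off-centre, and training only on perfectly centred calls measurably costs
scan recall. Noise snippets contain background only, with half of the
seismic ones carrying footfall transients: the noise class deliberately
emphasizes motion-induced signals, because broadband transients are the
confusable negatives a deployed scanner must reject, and under-representing
them measurably costs scan precision. Day and night conditions are mixed
1:1 within each class.

Continuous scanning slides 12-s windows at a configurable hop (4 s in the
analysis scripts), classifies each rendered window, and merges runs of
consecutive windows whose rumble probability exceeds 0.5 into one detection
at the run's peak-score centre. The threshold and run-merging rule are
package decisions; detections are scored against truth onsets with a ±6-s
tolerance (half a window).

## Catalog analytics

Events (one frequency/duration pick each) merge into rumbles when their
time intervals overlap the group's common window and their frequency ratio
to the group's lowest frequency is within 15% of an integer — a tolerance
chosen to merge the fundamental and harmonics of one call without merging
distinct calls ≥ 5 s apart; no grouping rule is prescribed by the source
material, so this one is stated and tested rather than inferred.

Inter-call gaps are measured start-to-start (configurable to end-to-start)
and binned into the six half-open intervals [0,5), [5,10), [10,30),
[30,60), [60,120), [120,∞) s; the final rumble, having no successor, counts
as > 120 s so that the six counts always partition the catalog. Motion
coincidence uses the ±50-s rule: a rumble is "yes" if any footfall time
falls within 50 s before its start or after its end; the automated labeler
is binary, and "not_sure" survives only when reading manual label files.
Cross-domain matching is greedy nearest-in-time one-to-one under ±2 s and
±2 Hz tolerances (declared defaults, not inferences); histogram similarity
is the intersection of unit-normalized histograms. The noise metric is
band-limited RMS per window. Each of these has an independent brute-force
oracle in the test suite that must agree exactly on 1000 random catalogs.

Feature estimation from spectrograms tracks the per-frame band-power ridge:
apex frequency at the ridge-power maximum, duration as the contiguous span
where the ridge exceeds the per-frequency median background by a factor of
5 *and* stays within 10 dB of the ridge peak, timestamp as the ridge-power
centroid. The background factor balances missing taper-dimmed call edges
against chasing noise excursions, and runs shorter than 0.75 s are
discarded as noise (pure noise readily produces single above-margin
frames). The 10-dB-of-peak floor anchors the measured duration to the
call's envelope: on a very quiet channel a background-relative threshold
alone inflates durations with SNR, which showed up as a systematic
duration bias on the infrasound side before the floor was added. At
amplitude SNR ≥ 5 the tests require ±1 spectral bin on apex and ±0.75 s on
duration in ≥ 90% of calls.

## Polarization

Band-passed three-component windows are summarized by the 3×3 zero-lag
covariance and its eigenstructure: `vh_ratio` = Z-energy / (N+E energy),
incidence of the dominant eigenvector, rectilinearity from the eigenvalue
spread. Under isotropic noise with equal per-component power the expected
ratio is exactly 0.5. Classification thresholds are therefore set at ≤ 0.25
for Love-like (half the isotropic value) and ≥ 2 for Rayleigh-like (four
times it); a threshold at 0.5 itself would classify half of all isotropic
windows as Love-like by symmetry, which is why the nominal
(0.5, 2) pair was rejected in favour of (0.25, 2).

## Problem sizes and what the tests show

The acceptance suite runs an end-to-end injection-recovery at study scale —
a 2-h scene with 60 calls and day/night noise, a classifier trained on
400+400 seismic snippets, recall ≥ 0.9 and precision ≥ 0.85 — plus
scaled-down versions of the cross-domain protocol (50+50 snippets per
domain) and the deterministic pipeline rerun (24+24 snippets, 400-s scene).
`scripts/acceptance.R` recomputes the same quantities at similar desk
scales (30-min scene, 150+150 snippets, 40+40 per domain for the
protocol). These sizes are the package's chosen operating points for a
single-CPU desk run.

Passing these tests shows that the implementation is internally coherent:
the generator writes what the catalog says, the preprocessing preserves
energy and geometry, the network can learn and generalize the synthetic
class boundary, and the analytics match independent oracles. It does not
show field performance: real rumbles vary in contour shape, harmonic
balance and coupling; real noise is non-Gaussian and non-stationary in ways
the three-component model (broadband + lines + bursts) does not capture;
and real picking errors have structure that uniform truth jitter does not.
Published accuracies on real zoo data are therefore not reproduction
targets for this artifact.

## Known limitations

* No physical wave propagation: no attenuation, dispersion, site response
  or sensor coupling; amplitudes are specified at the sensor.
* No instrument response simulation or removal (consistent with treating
  amplitudes as already-calibrated physical units).
* miniSEED I/O is not provided; waveforms interchange as CSV with a
  metadata header.
* The scanner's run-merging can fuse calls closer than one window length
  into a single detection; scheduled scenes keep calls separable by
  default, and the scorer tolerates fused detections covering two truths.
* The CNN is single-threaded by design for reproducibility; wall-clock
  training cost scales linearly with the training-set size.
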