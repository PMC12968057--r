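# rumbleR

Seismo-acoustic detection and monitoring of elephant rumbles.

African elephants vocalize in rumbles: tonal calls with a fundamental
frequency of roughly 10–25 Hz and harmonics above, lasting 1–8 s, that
radiate both as airborne infrasound and as seismic ground motion of a few
µm/s. A co-located three-component seismometer and infrasound sensor can
therefore monitor vocal activity around the clock — and the seismic channel
additionally records locomotion (footfall) transients that pressure sensors
cannot see. The practical obstacles are anthropogenic noise (daytime
seismic noise at a zoo rises by a factor of 5–10, with monochromatic
machine lines inside the call band) and the cost of picking calls by hand.

`rumbleR` implements the full analysis chain for this monitoring problem,
exercisable end-to-end with no field data:

* **Scene synthesis** (`render_scene()`): paired three-component seismic +
  infrasound records with exact ground truth — tonal rumbles with harmonic
  stacks and frequency contours, seismic-only footfalls, diurnal noise with
  machine lines and daytime bursts, alternating-night activity schedules.
* **Preprocessing** (`bandpass_filter()`, `compute_spectrogram()`,
  `average_component_maps()`, `render_snippet_image()`): 1–80 Hz zero-phase
  filtering, calibrated PSD spectrograms, N/E/Z averaging, and 12-s
  snippets rendered as fixed 232 × 115 RGB images.
* **Classification** (`build_model()`, `train_cnn()`, `run_protocol()`,
  `scan_continuous()`): a six-convolution CNN (32/32 @5×5, 64/64 @3×3,
  128/128 @5×5, each block pooled and dropped out; dense-128; 2-class
  softmax; 7,350,434 parameters) trained with RMSprop on rumble/noise
  snippet images; within-domain, cross-domain and combined (S-/I-/C-CNN)
  evaluation; sliding-window scanning of continuous records. The network
  is implemented natively in C++/BLAS — no external deep-learning runtime —
  and trains bit-reproducibly under a seed.
* **Catalog analytics** (`group_events_to_rumbles()`,
  `interval_histogram()`, `label_motion()`, `activity_series()`,
  `noise_profile()`, `match_cross_domain()`, `histogram_similarity()`,
  `estimate_event_features()`): the event/rumble data model and the
  temporal statistics used to characterize vocal activity.
* **Polarization** (`particle_motion()`, `classify_band_polarization()`):
  covariance eigen-analysis of band-passed three-component windows,
  separating Rayleigh-like (vertical) from Love-like (horizontal) coupling
  per frequency band.

The `analysis/` directory holds numbered drivers (`01_simulate_scene.R` …
`07_polarization.R`) that run the whole study on synthetic data and write
tables under `results/`; `run_pipeline()` offers the same flow as a single
configurable, manifest-writing call.

## Worked example

Train a classifier on synthetic seismic snippets and scan a fresh 10-minute
scene:

```r
library(rumbleR)

imgs  <- synth_snippet_set(60, 60, "seismic", seed = 11)
cfg   <- train_config(seed = 42)
sp    <- split_dataset(imgs, cfg)
model <- train_cnn(build_model(seed = 42), sp$train, sp$val, cfg)
tail(model$history, 1)
#>   train_loss train_acc   val_loss val_acc
#> 5 0.07043594 0.9880952 0.02848838       1

scene <- render_scene(scene_config(duration = 600, seed = 9,
                                   clock_start_hour = 6.9, n_rumbles = 6))
det <- scan_continuous(list(scene$seismic_N, scene$seismic_E,
                            scene$seismic_Z), model, hop = 4)
score_detections(det, scene$truth$onset_time[scene$truth$type == "rumble"])
#> $recall
#> [1] 1
#> $precision
#> [1] 0.5454545
#> $n_truth
#> [1] 6
#> $n_detections
#> [1] 11
```

Training converges in five epochs (validation accuracy 1.0 above); the
scan returns detection times and scores, and `score_detections()` reports
recall/precision against the injected truth with a ±6-s tolerance. With
only 60 training calls the scanner finds every injected rumble (recall
1.0) but also flags other transients; precision rises with training-set
size as the network sees more footfall and daytime-burst examples in the
noise class — at the study scale (400+400 snippets, 2-h scene, 60 calls)
the same pipeline reaches recall 0.97 at precision 0.98, which is what the
acceptance suite asserts.

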