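#!/usr/bin/env Rscript
# Apply the trained network to the continuous 2-h scene: slide 12-s windows
# at a 4-s hop over the averaged seismic spectrograms, merge above-threshold
# runs into detections, and score recall/precision against the injected
# truth catalog.

library(rumbleR)

out <- "results/detection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

traces <- read_waveforms(file.path("results/scene", c(
  "seismic_N.csv", "seismic_E.csv", "seismic_Z.csv")))
truth <- utils::read.csv("results/scene/truth_catalog.csv")
model <- load_checkpoint("results/classifier/model_checkpoint.json")

det <- scan_continuous(traces, model, hop = 4, threshold = 0.5)
utils::write.csv(cbind(det, domain = rep("seismic", nrow(det))),
                 file.path(out, "detections.csv"), row.names = FALSE)
ws <- attr(det, "window_scores")
utils::write.csv(ws, file.path(out, "window_scores.csv"), row.names = FALSE)

onsets <- truth$onset_time[truth$type == "rumble"]
s <- score_detections(det, onsets)
message(sprintf(
  "%d detections for %d injected rumbles: recall %.2f, precision %.2f.",
  s$n_detections, s$n_truth, s$recall, s$precision))
jsonlite::write_json(s, file.path(out, "detection_score.json"),
                     digits = NA, auto_unbox = TRUE)
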