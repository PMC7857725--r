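#!/usr/bin/env Rscript
# Eye-movement confound screen: detect saccades (4 degrees within 4 ms) and
# cue-fixation epochs from the 1 kHz eye trace, then flag units with
# saccade-direction-tuned activity (Kruskal-Wallis over 8 direction bins) or
# fixation-onset responses (one-sided signed-rank). Flagged units are
# excluded from the premotor analyses.

suppressPackageStartupMessages(library(premovoc))

s <- read_session("results/session")
saccades <- detect_saccades(s$eye)
message(sprintf("detected %d saccades (median amplitude %.1f deg)",
                nrow(saccades), median(saccades$amplitude)))

scr <- screen_units(s, saccades = saccades)
write.csv(scr, "results/screen.csv", row.names = FALSE)
message(sprintf(
  "screened %d units: %d saccade-tuned, %d fixation-locked, %d excluded",
  nrow(scr), sum(scr$is_saccade_unit), sum(scr$is_fixation_unit),
  sum(scr$excluded)))
message("wrote results/screen.csv")
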