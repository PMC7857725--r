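#!/usr/bin/env Rscript
# Simulate one labeled recording session of the vocal/manual go-nogo task
# and persist it as a session bundle for the downstream analysis scripts.
#
# The session uses the task's study conditions: blocks alternating after 25
# hits, 1-5 s pre-cue, 3 s go epoch, 20% catch trials, ~50% vocal and 100%
# manual hit rates, lognormal reaction times (means ~1.8 s vocal, ~0.52 s
# manual), spontaneous inter-trial responses, and a 1 kHz eye trace.

suppressPackageStartupMessages(library(premovoc))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cfg <- sim_config(
  n_blocks = 4,
  n_units = c(PMrv = 10L, ASi = 12L, VPA = 14L),
  seed = seed)

message("simulating session (seed ", seed, ") ...")
sim <- generate_session(cfg)
s <- sim$session

dir.create("results", showWarnings = FALSE)
write_session(s, "results/session")

truth <- data.frame(
  unit_id = vapply(sim$truth$profiles, `[[`, "", "unit_id"),
  area = vapply(sim$truth$profiles, `[[`, "", "area"),
  selectivity = vapply(sim$truth$profiles, `[[`, "", "selectivity"),
  sign_vocal = vapply(sim$truth$profiles, `[[`, "", "sign_vocal"),
  sign_hand = vapply(sim$truth$profiles, `[[`, "", "sign_hand"),
  baseline_rate = vapply(sim$truth$profiles, `[[`, 0, "baseline_rate"),
  saccade_gain = vapply(sim$truth$profiles, `[[`, 0, "saccade_gain"),
  fixation_gain = vapply(sim$truth$profiles, `[[`, 0, "fixation_gain"))
write.csv(truth, "results/unit_truth.csv", row.names = FALSE)

message(sprintf(
  "session: %d trials over %.0f s, %d units, %d spontaneous events",
  nrow(s$trials), s$duration, length(s$units), nrow(s$spontaneous)))
message(sprintf("ground-truth classes: %s",
                paste(names(table(truth$selectivity)),
                      table(truth$selectivity), collapse = ", ")))
message("bundle written to results/session/")
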