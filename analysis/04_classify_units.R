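#!/usr/bin/env Rscript
# Premotor response-type classification. Eligible units (rate > 1 Hz, >= 7
# hits per block, not eye-excluded, no go-cue preference) are tested for
# modulation in the 450 ms before response onset against the 450 ms pre-cue
# baseline (two-sided Wilcoxon signed-rank, p < 0.05), signed
# excited/suppressed, and assigned PSTH latencies where the 20-consecutive-
# bin threshold rule is met. The cued-vs-spontaneous contrast is attached
# for classified units. Accuracy against the generator's ground truth is
# reported alongside.

suppressPackageStartupMessages(library(premovoc))

s <- read_session("results/session")
scr <- read.csv("results/screen.csv")
cl <- classify_units(s, scr)
write.csv(cl, "results/classification.csv", row.names = FALSE)

truth <- read.csv("results/unit_truth.csv")
m <- match(cl$unit_id, truth$unit_id)
true_vocal <- truth$selectivity[m] %in% c("vocal", "both")
true_hand <- truth$selectivity[m] %in% c("hand", "both")
ok <- cl$eligible
message(sprintf("eligible units: %d / %d", sum(ok), nrow(cl)))
message(sprintf(
  "vocal: %d called (%d true); hand: %d called (%d true); both: %d",
  sum(cl$is_vocal), sum(true_vocal & ok), sum(cl$is_hand),
  sum(true_hand & ok), sum(cl$is_both)))
lat <- cl$psth_latency_vocal[!is.na(cl$psth_latency_vocal)]
if (length(lat)) {
  message(sprintf("vocal PSTH latencies determined for %d units (median %.2f s)",
                  length(lat), median(lat)))
} else {
  message("no vocal PSTH latency met the 20-consecutive-bin rule")
}

# normalized rectified population curve for vocal-correlated units
if (any(cl$is_vocal)) {
  pc <- population_curve(s, cl, "vocal")
  write.csv(data.frame(time = pc$times, mean = pc$mean, sem = pc$sem),
            "results/population_curve_vocal.csv", row.names = FALSE)
  premotor <- pc$times >= -0.45 & pc$times < 0
  message(sprintf(
    "population curve (n=%d): baseline mean %.2f, premotor mean %.2f (z units)",
    pc$n_units, mean(pc$mean[pc$times < -1.5]), mean(pc$mean[premotor])))
}
message("wrote results/classification.csv")
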