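#!/usr/bin/env Rscript
# Time-resolved coding quality of classified units: AUROC between vocal and
# manual trial rates in 200 ms windows stepped by 10 ms over [-2, 1] s
# around response onset, with a 1000-permutation null, coding latency (first
# of 3 consecutive significant windows) and strength (mean |AUROC - 0.5| in
# the 450 ms premotor epoch).

suppressPackageStartupMessages(library(premovoc))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

s <- read_session("results/session")
cl <- read.csv("results/classification.csv")
ids <- cl$unit_id[cl$is_vocal | cl$is_hand]
message("running sliding ROC for ", length(ids), " classified units ...")

rows <- list()
summ <- list()
for (id in ids) {
  u <- s$units[[match(id, vapply(s$units, `[[`, "", "unit_id"))]]
  r <- roc_analysis(u, s, n_perm = 1000,
                    seed = derive_seed(seed, paste0("roc_", id)))
  rows[[id]] <- data.frame(unit_id = id, window_center = r$window_centers,
                           auroc = r$auroc, lower = r$lower,
                           upper = r$upper, significant = r$significant)
  summ[[id]] <- data.frame(unit_id = id, latency = r$latency,
                           strength = r$strength)
  message(sprintf("  %s: latency %s s, strength %.3f", id,
                  ifelse(is.na(r$latency), "n/a",
                         sprintf("%.2f", r$latency)), r$strength))
}
write.csv(do.call(rbind, rows), "results/roc_traces.csv", row.names = FALSE)
write.csv(do.call(rbind, summ), "results/roc_summary.csv", row.names = FALSE)
message("wrote results/roc_traces.csv and results/roc_summary.csv")
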