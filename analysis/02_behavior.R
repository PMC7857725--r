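#!/usr/bin/env Rscript
# Behavioral performance of the simulated session: hit and false-alarm
# rates, d-prime sensitivity per response type, and reaction-time summaries.
# A d-prime of at least 1.5 indicates the subject is under stimulus control.

suppressPackageStartupMessages(library(premovoc))

s <- read_session("results/session")
bs <- behavior_summary(s)
write.csv(bs, "results/behavior.csv", row.names = FALSE)

for (i in seq_len(nrow(bs))) {
  message(sprintf(
    "%-6s block: HR %.1f%% (%d/%d), FA %.1f%% (%d/%d), d' = %.2f%s, RT %.2f +/- %.2f s",
    bs$block[i], 100 * bs$hit_rate[i], bs$n_hits[i], bs$n_go[i],
    100 * bs$fa_rate[i], bs$n_fa[i], bs$n_fa_opportunities[i],
    bs$d_prime[i], ifelse(bs$above_threshold[i], " (above 1.5)", ""),
    bs$rt_mean[i], bs$rt_sd[i]))
}
message("wrote results/behavior.csv")
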