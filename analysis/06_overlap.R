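#!/usr/bin/env Rscript
# Population overlap: do vocal- and hand-selectivity co-occur in single
# units more often than the product of their marginal proportions predicts?
# Reports both chance variants (bare product and direction-matched), the
# one-sided exact binomial test, and the chi-squared comparison of vocal vs
# hand prevalence, per area.

suppressPackageStartupMessages(library(premovoc))

cl <- read.csv("results/classification.csv")
ov <- overlap_report(cl)
write.csv(ov, "results/overlap.csv", row.names = FALSE)

for (i in seq_len(nrow(ov))) {
  message(sprintf(
    "%-5s n=%3d: vocal %.1f%%, hand %.1f%%, both %d (chance %.1f%%/%.1f%% dir), binom p=%s",
    ov$area[i], ov$n_total[i], 100 * ov$p_vocal[i], 100 * ov$p_hand[i],
    ov$n_both[i], 100 * ov$p0_chance[i], 100 * ov$p0_chance_dir[i],
    ifelse(is.na(ov$binom_p[i]), "n/a", sprintf("%.3f", ov$binom_p[i]))))
}
message("wrote results/overlap.csv")
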