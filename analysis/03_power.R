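#!/usr/bin/env Rscript
# Design-stage power computations for the three experiments: required
# sample sizes for the anticipated effect sizes and the sensitivity
# (critical effect size) of the n = 16 designs.

library(simonlca)

tab <- data.frame(
  quantity = c("n required, d = 1.0 (two-sided, power .9)",
               "n required, d = 0.7 (two-sided, power .9)",
               "critical d at n = 16 (one-sided, power .9)"),
  value = c(minimum_sample_size(1, 0.05, 0.9, tails = 2),
            minimum_sample_size(0.7, 0.05, 0.9, tails = 2),
            round(critical_effect_size(16, 0.05, 0.9, tails = 1), 3)))
print(tab, row.names = FALSE)
dir.create("results", showWarnings = FALSE)
write.csv(tab, file.path("results", "power.csv"), row.names = FALSE)
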