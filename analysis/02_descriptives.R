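#!/usr/bin/env Rscript
# Observed-data analysis chain on the synthetic datasets written by
# 01_simulate.R: outlier screening, per-condition error percentages and
# mean RTs, Simon effects per frequency class, and pooled delta plots with
# orthogonal-polynomial coefficients. Tables land in results/descriptives/.

library(simonlca)

in_dir <- file.path("results", "data")
out_dir <- file.path("results", "descriptives")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (nm in c("exp1", "exp2", "exp3")) {
  csv <- file.path(in_dir, paste0(nm, "_trials.csv"))
  if (!file.exists(csv)) {
    cat("skipping", nm, "- run analysis/01_simulate.R first\n")
    next
  }
  trials <- read_trials_csv(csv)
  obs <- summarize_observed(trials)

  cond_tab <- do.call(rbind, lapply(obs, function(o)
    data.frame(frequency_class = o$frequency_class,
               congruency = o$congruency, n = o$n,
               error_pct = round(o$error_pct, 2),
               mean_rt = round(mean(o$rts), 1))))
  write.csv(cond_tab, file.path(out_dir, paste0(nm, "_conditions.csv")),
            row.names = FALSE)

  simon <- c(frequent = mean(obs$frequent_incongruent$rts) -
               mean(obs$frequent_congruent$rts),
             infrequent = mean(obs$infrequent_incongruent$rts) -
               mean(obs$infrequent_congruent$rts))
  cat(sprintf("%s: Simon effect %5.1f ms (frequent) vs %5.1f ms (infrequent), modulation %5.1f ms\n",
              nm, simon["frequent"], simon["infrequent"],
              simon["frequent"] - simon["infrequent"]))

  dp <- do.call(rbind, lapply(c("frequent", "infrequent"), function(fc) {
    d <- delta_plot(obs[[paste0(fc, "_congruent")]]$rts,
                    obs[[paste0(fc, "_incongruent")]]$rts)
    data.frame(frequency_class = fc, p = d$probs,
               mean_ms = round(d$means, 1), delta_ms = round(d$deltas, 2),
               c0 = round(d$c0, 3), c1 = round(d$c1, 3),
               c2 = round(d$c2, 3))
  }))
  write.csv(dp, file.path(out_dir, paste0(nm, "_delta_plots.csv")),
            row.names = FALSE)
}
cat("condition summaries and delta plots written to", out_dir, "\n")
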