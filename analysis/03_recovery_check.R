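#!/usr/bin/env Rscript
# Compare the estimated component summaries from 02_model_and_summaries.R
# against the simulated truth written by 01_simulate.R.

source(file.path("analysis", "00_config.R"))

truth <- read.csv(file.path(cfg$data_dir, "true_summaries.csv"))
est <- read.csv(file.path(cfg$table_dir, "component_summaries.csv"), skip = 1)

m <- match(truth$component, est$component)
recov <- data.frame(
  component = truth$component,
  true_mean = truth$mean_score,
  est_mean = est$mean_score[m],
  mean_error = est$mean_score[m] - truth$mean_score,
  true_pct_at_max = truth$pct_at_max,
  est_pct_at_max = est$pct_at_max[m],
  pct_at_max_error = est$pct_at_max[m] - truth$pct_at_max
)
write.csv(recov, file.path(cfg$table_dir, "recovery.csv"), row.names = FALSE)

cat("component-mean errors (estimate - truth):\n")
print(recov[, c("component", "mean_error", "pct_at_max_error")], digits = 3)
cat(sprintf("max |mean error| = %.3f points; max |pct-at-max error| = %.2f pp\n",
            max(abs(recov$mean_error)), max(abs(recov$pct_at_max_error))))
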