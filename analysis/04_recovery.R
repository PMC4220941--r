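#!/usr/bin/env Rscript
# Step 4: simulation-based calibration of the full pipeline.
#
# Repeats generate -> design -> fit -> summarise over seeded replicates of
# the default scenario and reports per-coefficient bias, RMSE, credible-
# interval coverage and significance rates. Eight replicates keep this step
# to a few minutes; the packaged acceptance script runs the full twenty.

library(whitepox)

rec <- recovery_experiment(scenario_config(seed = 2003), n_replicates = 8)
write.csv(rec$summary, "results/recovery_summary.csv", row.names = FALSE)
write.csv(rec$replicates, "results/recovery_replicates.csv",
          row.names = FALSE)

print(rec)
cat(sprintf("\npooled 95%% CI coverage: %.1f%%\n",
            100 * sum(rec$summary$n_covered) / sum(rec$summary$n)))
cat("tables written to results/recovery_*.csv\n")
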