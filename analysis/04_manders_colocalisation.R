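#!/usr/bin/env Rscript
# Manders colocalisation analysis: rolling-ball background subtraction
# (radius 50 px), isodata selection on the green reference channel, and the
# intensity-weighted M1 coefficient against the red channel's threshold,
# summarised over three replicate fields per condition.
# Expectation: the high-overlap condition recovers M1 ~ 0.75, the
# low-overlap condition M1 ~ 0.20.

library(cocciq)

cfg <- pipeline_config("results/synthetic", seed = 1)
out <- run_coloc(cfg)

cat("Per-field M1:\n")
print(out$per_field, digits = 4)
cat("\nSummary over replicate fields:\n")
print(out$summary, digits = 4)
cat("\nTables: results/synthetic/coloc/coloc_results.csv, coloc_summary.csv\n")
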