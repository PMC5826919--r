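#!/usr/bin/env Rscript
# Donor-photobleaching FRET analysis: fit a mono-exponential decay with
# offset to every bleach trace, average time constants within each arm, and
# report E = 1 - tau_PB / tau'_PB per acceptor arm with a bootstrap CI.
# Expectation: the interacting arm recovers E ~ 20%, the non-interacting
# arm E ~ 0%.

library(cocciq)

cfg <- pipeline_config("results/synthetic", seed = 1)
out <- run_fret(cfg)

cat(sprintf("Converged decay fits: %d / %d\n", sum(out$fits$converged),
            nrow(out$fits)))
cat("\nFRET efficiencies per acceptor arm:\n")
print(out$results, digits = 4)
cat("\nTables: results/synthetic/fret/decay_fits.csv, fret_results.csv\n")
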