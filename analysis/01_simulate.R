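#!/usr/bin/env Rscript
# Generate the working cohort: 45 synthetic tumor exomes on the toy genome,
# with planted burdens, arm events, chromothripsis clusters, double-minute
# amplicons and signature mixtures. Writes all input tables plus the
# ground-truth manifest under results/cohort/.

library(gliomaburden)

cfg <- cohort_config(seed = 17, n_samples = 45)
sim <- simulate_cohort(cfg, dir = "results/cohort")

cat("cohort written to results/cohort/\n")
cat("  samples:   ", cfg$n_samples, "\n")
cat("  variants:  ", nrow(sim$variants), "\n")
cat("  segments:  ", nrow(sim$segments), "\n")
cat("  SV records:", nrow(sim$sv), "\n")
cat("  planted CT samples:",
    sum(sapply(sim$manifest$samples, function(s) s$ct$present)), "\n")
cat("  planted DM samples:",
    sum(sapply(sim$manifest$samples, function(s) s$dm$present)), "\n")
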