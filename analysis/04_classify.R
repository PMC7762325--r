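#!/usr/bin/env Rscript
# Molecular subset classification of the packaged 45-specimen cohort sheet:
# mGBM = TERT promoter mutation and/or EGFR amplification and/or 7+/10-.
# Discordances between the marker rule and the curated label are surfaced;
# the curated label takes precedence. Writes results/subset_calls.tsv.

library(gliomaburden)

sheet <- cohort_sheet()
cl <- withCallingHandlers(
  classify_subset(sheet),
  warning = function(w) {
    cat("NOTE:", conditionMessage(w), "\n")
    invokeRestart("muffleWarning")
  })
dir.create("results", showWarnings = FALSE)
write.table(cl, "results/subset_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

primary <- sheet$primary_status == "primary"
cat("specimens:", nrow(sheet), " patients:",
    length(unique(sheet$patient_id)), "\n")
cat("subset counts:\n")
print(table(cl$subset))
cat("among primary tumors:\n")
print(table(cl$subset[primary]))
cat("written: results/subset_calls.tsv\n")
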