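#!/usr/bin/env Rscript
# Step 1: simulate a synthetic two-day recall survey.
#
# Generates a survey emulating the structure of a national dietary survey
# (demographics with analytic and jackknife replicate weights, one or two
# 24-hour recalls per person, a 30-day supplement inventory) together with
# the generating truth, and writes the tables under results/survey/.

library(masafort)

cfg <- generator_config(n_persons = 2000, n_replicates = 32, seed = 2026)
survey <- generate_survey(cfg)

out <- "results/survey"
write_survey(survey, out)

cat("Synthetic survey written to", out, "\n")
cat(sprintf("  persons: %d, recall rows: %d, supplement rows: %d\n",
            nrow(survey$demographics), nrow(survey$recalls),
            nrow(survey$supplements)))
cat("Generating-truth UL exceedance (current vs fortified at 140 ug/100 g):\n")
print(survey$truth$exceedance, row.names = FALSE)
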