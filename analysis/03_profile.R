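#!/usr/bin/env Rscript
# Aggregates per-limb metrics into the median/range profile table, for both
# the measured synthetic limbs (02_measure_limbs.R output) and the shipped
# published reference rows, and prints the two median rows side by side.

suppressPackageStartupMessages(library(stiflemorph))

dir.create("results", showWarnings = FALSE)

# synthetic study set
syn <- read_limb_table("results/per_limb_metrics.csv")
write_profile(syn, "results/synthetic_profile.csv")
cat("synthetic profile -> results/synthetic_profile.csv\n")

# published reference rows
ref <- reference_limbs()
write_profile(ref, "results/reference_profile.csv")
cat("reference profile -> results/reference_profile.csv\n")

s_syn <- summarize_limbs(syn)
s_ref <- summarize_limbs(ref)
cmp <- rbind(synthetic_median = round_half_away(s_syn$median, 1),
             reference_median = round_half_away(s_ref$median, 1))
print(cmp)
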