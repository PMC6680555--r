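#!/usr/bin/env Rscript
# Compare the six pretreatment methods (raw, SNV, FD, SD, SNV-FD, SNV-SD)
# per block by PLS-DA calibration quality (R2, Q2, RMSEE, RMSECV, accuracy,
# aggregated by rank sum) and record the winner for each block.

library(irfuse)

dir.create("results", showWarnings = FALSE)
ftmir <- read_block("results/data/ftmir.csv", "FTMIR")
nir <- read_block("results/data/nir.csv", "NIR")

split <- split_by_class(list(ftmir, nir))
rk_f <- rank_pretreatments(ftmir, split, seed = 1)
rk_n <- rank_pretreatments(nir, split, seed = 1)

out <- rbind(cbind(block = "FT-MIR", rk_f$reports),
             cbind(block = "NIR", rk_n$reports))
write.csv(out, "results/pretreatment_ranking.csv", row.names = FALSE)
print(out, digits = 3)
message(sprintf("best pretreatment: FT-MIR %s, NIR %s", rk_f$best, rk_n$best))
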