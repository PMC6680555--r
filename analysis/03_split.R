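#!/usr/bin/env Rscript
# Deterministic per-class 2:1 Kennard-Stone split on the autoscaled
# concatenation of both blocks; the one assignment every later model reuses.

library(irfuse)

ftmir <- read_block("results/data/ftmir.csv", "FTMIR")
nir <- read_block("results/data/nir.csv", "NIR")
split <- split_by_class(list(ftmir, nir))
print(split)
write.csv(data.frame(sample_id = split$sample_id, role = split$role),
          "results/split_assignment.csv", row.names = FALSE)
message(sprintf("%d calibration / %d validation",
                sum(split$role == "calibration"),
                sum(split$role == "validation")))
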