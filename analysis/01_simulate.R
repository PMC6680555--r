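#!/usr/bin/env Rscript
# Simulate the two study-sized spectral blocks (FT-MIR 196 x 1150,
# NIR 196 x 1545; class sizes 40/40/36/40/40) and the block-complementary
# scenario with its ground-truth discriminative-variable masks, and write
# them as wide CSVs under results/data/.

library(irfuse)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 1

blocks <- simulate_blocks(seed = seed)
write_block(blocks$ftmir, "results/data/ftmir.csv")
write_block(blocks$nir, "results/data/nir.csv")
message(sprintf("default scenario: FT-MIR %d x %d, NIR %d x %d",
                nrow(blocks$ftmir$X), ncol(blocks$ftmir$X),
                nrow(blocks$nir$X), ncol(blocks$nir$X)))

sc <- make_complementary_scenario(seed = seed)
write_block(sc$ftmir, "results/data/complementary_ftmir.csv")
write_block(sc$nir, "results/data/complementary_nir.csv")
jsonlite::write_json(
  list(seed = seed,
       mask_ftmir = which(sc$mask_ftmir), mask_nir = which(sc$mask_nir),
       mask_wavenumbers_ftmir = sc$ftmir$grid[sc$mask_ftmir],
       mask_wavenumbers_nir = sc$nir$grid[sc$mask_nir]),
  "results/data/complementary_truth.json", auto_unbox = TRUE, digits = NA)
message(sprintf("complementary scenario: %d + %d ground-truth marker columns",
                sum(sc$mask_ftmir), sum(sc$mask_nir)))
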