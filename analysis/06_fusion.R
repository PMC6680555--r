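#!/usr/bin/env Rscript
# Low-, mid- and high-level fusion of the two blocks on the complementary
# scenario (PCs and VIP routes; the RFE/Boruta routes are timed separately
# in 05_selection.R) and the per-class efficiency / accuracy report tables.

library(irfuse)

cfg <- default_config(seed = 1, scenario = "complementary",
                      pretreat = list(ftmir = "SNV", nir = "SNV"),
                      selections = c("pcs", "vip"),
                      fusion_levels = c("low", "mid", "high"))
res <- run_experiment(cfg)
write_run(res, "results/fusion")
val <- res$report[res$report$set == "validation", c("dataset", "model", "accuracy")]
val$accuracy <- format_percent(val$accuracy)
print(val, row.names = FALSE)
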