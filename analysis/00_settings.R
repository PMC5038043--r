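# Shared settings for the analysis drivers: run the scripts in order from
# the repository root, e.g. `Rscript analysis/01_simulate_cohort.R`.
library(plaquenet)

SEED <- 1
DATA_DIR <- "results/analysis/data"
OUT_DIR <- "results/analysis"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

# stage-specific sub-seeds, fixed so each driver is reproducible alone
set.seed(SEED)
SEEDS <- as.list(sample.int(2^31 - 2, 10))
names(SEEDS) <- c("metadata", "counts", "sequences", "diversity",
                  "networks", "permutations", "layout", "summed",
                  "extra1", "extra2")
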