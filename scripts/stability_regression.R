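#!/usr/bin/env Rscript
# Full-scale replicate-stability regression: 20 seeded replicates of the
# reference scenario (3-mm domain, 130 hr, Tp = 50 hr, b* = 0.5,
# Fr = 50%), each classified at end time.  Expected counts: about 19/20
# plume-positive, 18/20 escape-positive, 0/20 necrotic-core-positive
# (binomial tolerance +/- 3).  Takes roughly half an hour per CPU.
#
# Usage: Rscript scripts/stability_regression.R [--seed <int>] [--out <path>]

suppressMessages(library(hypoxfate))

args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(arg_of("--seed", "1"))
out_path <- arg_of("--out", "results/stability.json")
dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(domain_um = 3000, init_radius_um = 250,
                       Tp = 3000, b_star = 0.5, Fr = 0.5,
                       end_time_hr = 130, snapshot_interval_hr = 130,
                       seed = seed)
t0 <- Sys.time()
st <- replicate_stability(cfg, n_replicates = 20)
elapsed <- as.numeric(difftime(Sys.time(), t0, units = "mins"))

cat(sprintf("plume %d/20, escape %d/20, necrotic core %d/20 (%.1f min)\n",
            st$counts[["plume"]], st$counts[["escape"]],
            st$counts[["necrotic_core"]], elapsed))
print(st$table[, c("seed", "plume", "escape", "necrotic_core",
                   "d_max_px", "A_px2", "F_N")])

ok <- st$counts[["plume"]] >= 19 - 3 &&
  st$counts[["escape"]] >= 18 - 3 &&
  st$counts[["necrotic_core"]] <= 3
jsonlite::write_json(
  list(plume_positive = unname(st$counts[["plume"]]),
       escape_positive = unname(st$counts[["escape"]]),
       necrotic_core_positive = unname(st$counts[["necrotic_core"]]),
       n = 20, pass = ok),
  out_path, auto_unbox = TRUE, digits = NA)
cat(if (ok) "PASS\n" else "FAIL\n")
if (!ok) quit(status = 1)
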