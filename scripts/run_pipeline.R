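#!/usr/bin/env Rscript

# Thin command-line wrapper over the package's pipeline:
#   Rscript scripts/run_pipeline.R --seed 7 --out results/run7 [--alpha 0.05]
# Simulates a cohort and a stained section, runs the full analysis and
# writes the report tables plus a JSON manifest to --out.

suppressMessages(library(mdcquant))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out", file.path("results", paste0("run", seed)))
alpha <- as.numeric(get_arg("--alpha", "0.05"))

cfg <- run_config(alpha = alpha, seed = seed)
report <- run_full(cfg)
print(report)
write_report(report, out_dir)
cat("report written to", out_dir, "\n")
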