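#!/usr/bin/env Rscript
# Grid-independence study for scenario 1 (single centred tumor, centre
# injection): runs the 50-minute session at successively refined meshes and
# reports the healthy-damage percentage at each.  The 256-interval run is
# long (order of an hour on one core); this study is intended as a nightly
# job, not part of the routine test suite.
#
# Usage: Rscript scripts/grid_independence.R [--meshes 64,128,256] [--out path.csv]

suppressPackageStartupMessages(library(thermoplan))

args <- commandArgs(trailingOnly = TRUE)
meshes <- c(64L, 128L, 256L)
out <- "results/grid_independence.csv"
i <- 1
while (i <= length(args)) {
  if (args[i] == "--meshes") { meshes <- as.integer(strsplit(args[i + 1], ",")[[1]]); i <- i + 2 }
  else if (args[i] == "--out") { out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}

rows <- lapply(meshes, function(N) {
  message("N = ", N, " ...")
  sc <- build_scenario(builtin_scenario(1, N = N))
  t0 <- proc.time()[["elapsed"]]
  r <- evaluate_injections(sc, c(0.050, 0.050, 0.050))
  data.frame(N = N, h = sc$domain$h, nodes = (N + 1)^3,
             Nt = r$Nt, Nh = r$Nh, beta = r$beta,
             seconds = round(proc.time()[["elapsed"]] - t0, 1))
})
tab <- do.call(rbind, rows)
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
write.csv(tab, out, row.names = FALSE)
print(tab)
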