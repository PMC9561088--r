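#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Generates the packaged synthetic landscape (seven correlated continuous
# layers + one categorical), plants four ecotype suitability surfaces with
# well-separated optima, and samples the village study design (16 districts
# x 2 villages). Writes the environmental stack, the sampling table, and
# the held-out district->ecotype truth under results/.

library(enmecotype)

seed <- as.integer(Sys.getenv("SEED", "1"))
out <- file.path("results", sprintf("run_seed%d", seed))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- synthetic_scenario(seed = seed)

write_stack(sc$stack, file.path(out, "stack"))
write.csv(sc$design$table, file.path(out, "villages.csv"), row.names = FALSE)
write.csv(sc$design$truth, file.path(out, "truth.csv"), row.names = FALSE)
for (k in seq_along(sc$suitability)) {
  write_grid(sc$suitability[[k]],
             file.path(out, sprintf("true_suitability_ecotype%d.asc", k)))
}
jsonlite::write_json(
  list(seed = seed, grid = c(64, 64),
       layers = names(sc$stack$layers),
       drivers = sc$truth$drivers,
       optima = sc$truth$optima, widths = sc$truth$widths),
  file.path(out, "scenario.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")

cat(sprintf(
  "simulated landscape: %d layers on a 64x64 grid; %d districts, %d villages\n",
  length(sc$stack$layers), length(unique(sc$design$table$district)),
  nrow(sc$design$table)))
cat("artefacts in", out, "\n")
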