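#!/usr/bin/env Rscript
# Stage 3 — model tuning and fitting.
#
# Splits the pooled occurrences 75/25, profiles feature-class x
# beta-multiplier candidates by small-sample-corrected AIC on the training
# part, then fits the pooled model and one niche model per district with
# the winning setting and writes their suitability maps.

library(enmecotype)

seed <- as.integer(Sys.getenv("SEED", "1"))
out <- file.path("results", sprintf("run_seed%d", seed))

stack <- read_stack(file.path(out, "stack", "manifest.csv"))
pooled <- read.csv(file.path(out, "occurrences.csv"))
screening <- jsonlite::read_json(file.path(out, "screening.json"),
                                 simplifyVector = TRUE)
selected <- screening$selected

part <- partition_occurrences(pooled, test_frac = 0.25, k = 10,
                              seed = stable_seed(seed, "partition"))
train <- pooled[part$train, ]
test <- pooled[part$test, ]
cat(sprintf("partition: %d training / %d test points, 10 regionalised folds\n",
            nrow(train), nrow(test)))

grid <- enumerate_grid(c("L", "LQ", "LQP"), c(1, 2, 4))
tuned <- tune_grid(stack, train, selected, grid, n_knots = 8)
write.csv(tuned, file.path(out, "tuning_grid.csv"), row.names = FALSE)
best <- select_best(tuned)
cat(sprintf("AICc selects fc = %s, beta multiplier = %g (AICc %.1f, K = %d)\n",
            best$fc_set, best$bm, best$AICc, best$K))

dir.create(file.path(out, "maps"), showWarnings = FALSE)
district_rows <- list()
for (d in unique(pooled$district)) {
  occ_d <- pooled[pooled$district == d, ]
  m <- fit_niche_model(stack, occ_d, vars = selected, fc_set = best$fc_set,
                       bm = best$bm, n_knots = 8)
  sm <- predict_suitability(m, stack)
  write_grid(sm$logistic, file.path(out, "maps", paste0(d, "_logistic.asc")))
  write_grid(sm$cumulative,
             file.path(out, "maps", paste0(d, "_cumulative.asc")))
  district_rows[[d]] <- data.frame(
    district = d, n_points = nrow(occ_d),
    auc_train = evaluate_model(m, stack)$auc_train,
    n_active_features = sum(m$lambda != 0))
}
district_tab <- do.call(rbind, district_rows)
write.csv(district_tab, file.path(out, "district_models.csv"),
          row.names = FALSE)
cat(sprintf("district models: training AUC %.3f-%.3f\n",
            min(district_tab$auc_train), max(district_tab$auc_train)))

jsonlite::write_json(list(fc_set = best$fc_set, bm = best$bm,
                          train_idx = part$train, test_idx = part$test,
                          fold = part$fold),
                     file.path(out, "tuning.json"), auto_unbox = TRUE,
                     digits = NA)
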