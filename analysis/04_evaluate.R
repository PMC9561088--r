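#!/usr/bin/env Rscript
# Stage 4 — pooled-model evaluation and variable importance.
#
# Refits the pooled model with the tuned setting and reports train/test
# AUC, ten-fold cross-validated AUC, jackknife gains (each variable alone /
# excluded), percent contribution from the fitting trace, permutation
# importance, and response curves.

library(enmecotype)

seed <- as.integer(Sys.getenv("SEED", "1"))
out <- file.path("results", sprintf("run_seed%d", seed))

stack <- read_stack(file.path(out, "stack", "manifest.csv"))
pooled <- read.csv(file.path(out, "occurrences.csv"))
screening <- jsonlite::read_json(file.path(out, "screening.json"),
                                 simplifyVector = TRUE)
tuning <- jsonlite::read_json(file.path(out, "tuning.json"),
                              simplifyVector = TRUE)
selected <- screening$selected
train <- pooled[tuning$train_idx, ]
test <- pooled[tuning$test_idx, ]

model <- fit_niche_model(stack, train, vars = selected,
                         fc_set = tuning$fc_set, bm = tuning$bm,
                         n_knots = 8)
ev <- evaluate_model(model, stack, test)
cat(sprintf("pooled model: training AUC %.3f, test AUC %.3f\n",
            ev$auc_train, ev$auc_test))

cv <- vapply(sort(unique(tuning$fold)), function(f) {
  m <- fit_niche_model(stack, train[tuning$fold != f, ], vars = selected,
                       fc_set = tuning$fc_set, bm = tuning$bm, n_knots = 8)
  evaluate_model(m, stack, train[tuning$fold == f, ])$auc_test
}, numeric(1))
cat(sprintf("regionalised 10-fold CV AUC: mean %.3f (range %.3f-%.3f)\n",
            mean(cv), min(cv), max(cv)))

contrib <- percent_contribution(model)
perm <- permutation_importance(model, stack,
                               seed = stable_seed(seed, "permimp"))
imp <- data.frame(variable = names(contrib),
                  percent_contribution = as.numeric(contrib),
                  permutation_importance = as.numeric(perm[names(contrib)]))
write.csv(imp, file.path(out, "importance.csv"), row.names = FALSE)
cat("top contributor:", imp$variable[which.max(imp$percent_contribution)],
    "\n")

jack <- jackknife_importance(stack, train, selected, test_occ = test,
                             fc_set = tuning$fc_set, bm = tuning$bm,
                             n_knots = 8)
write.csv(jack$table, file.path(out, "jackknife.csv"), row.names = FALSE)

curves <- do.call(rbind, lapply(selected, function(v) {
  response_curve(model, stack, v)
}))
write.csv(curves, file.path(out, "response_curves.csv"), row.names = FALSE)

jsonlite::write_json(list(auc_train = ev$auc_train, auc_test = ev$auc_test,
                          gain_train = ev$gain_train, cv_auc = cv),
                     file.path(out, "evaluation.json"), auto_unbox = TRUE,
                     digits = NA)
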