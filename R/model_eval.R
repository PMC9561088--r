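# Model accuracy and variable importance: rank-based AUC, jackknife gains,
# percent contribution from the fitting trace, permutation importance, and
# response curves.

#' Rank-based AUC of presence vs background scores
#'
#' The Mann-Whitney probability that a presence outscores a background cell,
#' with ties counted one half. Invariant to monotone transforms of the
#' scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0) {
    stop("empty score vector", call. = FALSE)
  }
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# gain of presences in `table` under `model` relative to a uniform background
gain_at <- function(model, table) {
  raw <- predict_scores(model, table, type = "raw")
  mean(log(raw)) + log(model$n_background)
}

# training AUC of a fitted model: presences vs its background cells
training_auc <- function(model, stack) {
  bg <- background_table(stack)[, model$vars, drop = FALSE]
  auc_rank(predict_scores(model, model$presence),
           predict_scores(model, bg))
}

#' Evaluate a fitted model on train/test occurrences
#'
#' @param model a model from [fit_niche_model()] (fitted on the training
#'   points).
#' @param stack the training [env_stack()].
#' @param test_occ held-out occurrence data.frame (`lon`, `lat`), or `NULL`.
#' @return list `auc_train`, `auc_test` (NA without test points),
#'   `gain_train`, `gain_test`.
#' @export
evaluate_model <- function(model, stack, test_occ = NULL) {
  bg <- background_table(stack)[, model$vars, drop = FALSE]
  bg_scores <- predict_scores(model, bg)
  out <- list(auc_train = auc_rank(predict_scores(model, model$presence),
                                   bg_scores),
              gain_train = model_gain(model)$gain,
              auc_test = NA_real_, gain_test = NA_real_)
  if (!is.null(test_occ) && nrow(test_occ) > 0) {
    ext <- extract_at(stack, test_occ)
    tst <- ext[ext$status == "ok", model$vars, drop = FALSE]
    if (nrow(tst) > 0) {
      out$auc_test <- auc_rank(predict_scores(model, tst), bg_scores)
      out$gain_test <- gain_at(model, tst)
    }
  }
  out
}

#' Jackknife variable importance
#'
#' For each selected variable, refits the model with that variable alone and
#' with it excluded, recording training gain, test gain and test AUC for
#' each sub-model alongside the all-variables reference.
#'
#' @param stack an [env_stack()].
#' @param occ training occurrences (`lon`, `lat`).
#' @param vars selected variables (>= 2 for without-models).
#' @param test_occ optional held-out occurrences.
#' @param fc_set,bm,n_knots,tol,max_sweeps model settings.
#' @return list with `table` (one row per (variable, mode) plus the
#'   reference row) and `reference` (the full model).
#' @export
jackknife_importance <- function(stack, occ, vars, test_occ = NULL,
                                 fc_set = "H", bm = 1, n_knots = 30,
                                 tol = 1e-7, max_sweeps = 500) {
  if (length(vars) < 2) {
    stop("jackknife needs at least two variables (without-model undefined)",
         call. = FALSE)
  }
  fit1 <- function(v) {
    fit_niche_model(stack, occ, vars = v, fc_set = fc_set, bm = bm,
                    n_knots = n_knots, tol = tol, max_sweeps = max_sweeps)
  }
  score <- function(model, variable, mode) {
    ev <- evaluate_model(model, stack, test_occ)
    data.frame(variable = variable, mode = mode,
               gain_train = ev$gain_train, gain_test = ev$gain_test,
               auc_train = ev$auc_train, auc_test = ev$auc_test,
               stringsAsFactors = FALSE)
  }
  ref <- fit1(vars)
  rows <- list(score(ref, "(all)", "reference"))
  for (v in vars) {
    rows[[length(rows) + 1]] <- score(fit1(v), v, "with_only")
    rows[[length(rows) + 1]] <- score(fit1(setdiff(vars, v)), v, "without")
  }
  list(table = do.call(rbind, rows), reference = ref)
}

#' Percent contribution of variables from the fitting trace
#'
#' Each accepted coordinate-descent update's decrease in the regularized
#' objective (equivalently, increase in regularized gain) is credited to the
#' updated feature's underlying variable(s); product features split their
#' credit evenly between the two variables. Credits are floored at zero and
#' normalized to sum to 100.
#'
#' @param model a `maxent_model` with a recorded update trace.
#' @param vars variables to report (default: the model's variables).
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model, vars = model$vars) {
  if (is.null(model$update_feature)) {
    stop("model carries no fitting trace", call. = FALSE)
  }
  if (is.null(vars)) vars <- unique(model$specs$var1)
  credit <- setNames(numeric(length(vars)), vars)
  sp <- model$specs
  for (i in seq_along(model$update_feature)) {
    j <- model$update_feature[i]
    d <- model$update_delta[i]
    v1 <- sp$var1[j]; v2 <- sp$var2[j]
    if (!is.na(v2)) {
      credit[v1] <- credit[v1] + d / 2
      credit[v2] <- credit[v2] + d / 2
    } else {
      credit[v1] <- credit[v1] + d
    }
  }
  credit <- pmax(credit, 0)
  tot <- sum(credit)
  if (tot <= 0) {
    # fully shrunk model: no credit anywhere, report uniform zeros
    return(setNames(rep(0, length(vars)), vars))
  }
  100 * credit / tot
}

#' Permutation importance of variables
#'
#' For each variable, its values are permuted jointly across presence and
#' background rows (seeded), the model is re-applied, and the drop in
#' training AUC recorded; drops are floored at zero and normalized to sum
#' to 100.
#'
#' @param model a model from [fit_niche_model()].
#' @param stack the training [env_stack()].
#' @param seed integer seed for the permutations.
#' @return Named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, stack, seed = 1) {
  bg <- background_table(stack)[, model$vars, drop = FALSE]
  pres <- model$presence
  n_bg <- nrow(bg)
  combined <- rbind(bg, pres)
  base_scores <- predict_scores(model, combined)
  auc0 <- auc_rank(base_scores[-seq_len(n_bg)], base_scores[seq_len(n_bg)])
  drops <- vapply(model$vars, function(v) {
    perm <- combined
    perm[[v]] <- with_seed(stable_seed(seed, v),
                           sample(perm[[v]], nrow(perm)))
    s <- predict_scores(model, perm)
    max(0, auc0 - auc_rank(s[-seq_len(n_bg)], s[seq_len(n_bg)]))
  }, numeric(1))
  tot <- sum(drops)
  if (tot <= 0) return(setNames(rep(0, length(drops)), model$vars))
  100 * drops / tot
}

#' Response curve of one variable
#'
#' Sweeps the variable over its background range at `n_grid` points while
#' holding all other variables at their background mean (mode for
#' categorical variables) and records the logistic output.
#'
#' @param model a model from [fit_niche_model()].
#' @param stack the training [env_stack()].
#' @param variable variable name in the model.
#' @param n_grid number of sweep points (default 100).
#' @return data.frame `variable, value, logistic`.
#' @export
response_curve <- function(model, stack, variable, n_grid = 100) {
  if (!variable %in% model$vars) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  bg <- background_table(stack)[, model$vars, drop = FALSE]
  ref <- lapply(setNames(model$vars, model$vars), function(v) {
    if (model$space$kind[[v]] == "categorical") {
      tab <- table(bg[[v]])
      as.numeric(names(tab)[which.max(tab)])
    } else {
      mean(bg[[v]])
    }
  })
  sweep_vals <- if (model$space$kind[[variable]] == "categorical") {
    sort(unique(bg[[variable]]))
  } else {
    seq(min(bg[[variable]]), max(bg[[variable]]), length.out = n_grid)
  }
  tab <- as.data.frame(ref)[rep(1, length(sweep_vals)), , drop = FALSE]
  tab[[variable]] <- sweep_vals
  data.frame(variable = variable, value = sweep_vals,
             logistic = predict_scores(model, tab, type = "logistic"),
             row.names = NULL, stringsAsFactors = FALSE)
}
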