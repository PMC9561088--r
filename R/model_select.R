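# Feature-class x beta-multiplier model selection by small-sample-corrected
# AIC, plus train/test partitioning with spatially structured folds.

#' Default feature-class grid
#'
#' All 15 non-empty subsets of \{L, Q, H, T\} plus the full set \{L,Q,P,H,T\}:
#' 16 feature-class combinations which, crossed with beta multipliers 1-12,
#' give the 192-candidate tuning grid.
#'
#' @return Character vector of feature-class strings.
#' @export
default_fc_sets <- function() {
  base <- c("L", "Q", "H", "T")
  sets <- character(0)
  for (size in 1:4) {
    cmb <- utils::combn(base, size)
    sets <- c(sets, apply(cmb, 2, paste, collapse = ""))
  }
  c(sets, "LQPHT")
}

#' Enumerate the model tuning grid
#'
#' Cartesian product of feature-class sets and beta multipliers in stable
#' order (fc list order crossed with ascending BM).
#'
#' @param fc_list character vector of feature-class strings
#'   (default [default_fc_sets()]).
#' @param bm_range numeric beta multipliers (default 1:12).
#' @return data.frame with columns `fc_set`, `bm`.
#' @export
enumerate_grid <- function(fc_list = default_fc_sets(), bm_range = 1:12) {
  if (length(fc_list) == 0) stop("empty feature-class list", call. = FALSE)
  if (length(bm_range) == 0) stop("empty beta-multiplier range",
                                  call. = FALSE)
  bm_range <- sort(bm_range)
  data.frame(fc_set = rep(fc_list, each = length(bm_range)),
             bm = rep(bm_range, times = length(fc_list)),
             stringsAsFactors = FALSE)
}

#' AICc of a fitted niche model
#'
#' `K` counts nonzero coefficients; the log-likelihood sums presence log raw
#' values with raw normalized over the study grid;
#' `AICc = 2K - 2 loglik + 2K(K+1)/(n - K - 1)`, flagged invalid when the
#' correction denominator is not positive (such models are never selected).
#'
#' @param model a `maxent_model` fitted by [fit_niche_model()].
#' @param n number of occurrence points (defaults to the model's presence
#'   count).
#' @return list `K, loglik, AICc, valid`.
#' @export
model_aicc <- function(model, n = model$n_presence) {
  K <- sum(model$lambda != 0)
  eta_pres <- sum(model$presence_means * model$lambda) * model$n_presence
  loglik <- eta_pres - model$n_presence * model$logZ
  valid <- (n - K - 1) > 0
  aicc <- if (valid) {
    2 * K - 2 * loglik + 2 * K * (K + 1) / (n - K - 1)
  } else {
    NA_real_
  }
  list(K = K, loglik = loglik, AICc = aicc, valid = valid)
}

#' Fit and score every candidate on the tuning grid
#'
#' @param stack an [env_stack()].
#' @param occ occurrence data.frame (`lon`, `lat`).
#' @param vars variables to model.
#' @param grid candidate data.frame from [enumerate_grid()].
#' @param n_knots,tol,max_sweeps passed to [fit_niche_model()].
#' @return data.frame `fc_set, bm, K, loglik, AICc, valid` in grid order.
#' @export
tune_grid <- function(stack, occ, vars, grid = enumerate_grid(),
                      n_knots = 30, tol = 1e-7, max_sweeps = 500) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- fit_niche_model(stack, occ, vars = vars, fc_set = grid$fc_set[i],
                         bm = grid$bm[i], n_knots = n_knots, tol = tol,
                         max_sweeps = max_sweeps)
    a <- model_aicc(m)
    data.frame(fc_set = grid$fc_set[i], bm = grid$bm[i], K = a$K,
               loglik = a$loglik, AICc = a$AICc, valid = a$valid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the best feature-class/beta-multiplier combination
#'
#' Minimum AICc among valid candidates; ties broken by smaller K, then
#' smaller BM, then grid order.
#'
#' @param grid_result data.frame from [tune_grid()].
#' @return One-row data.frame (the winning candidate).
#' @export
select_best <- function(grid_result) {
  ok <- grid_result[grid_result$valid & is.finite(grid_result$AICc), ,
                    drop = FALSE]
  if (nrow(ok) == 0) stop("no valid candidate model on the grid",
                          call. = FALSE)
  ord <- order(ok$AICc, ok$K, ok$bm, seq_len(nrow(ok)))
  ok[ord[1], , drop = FALSE]
}

#' Train/test split with spatially structured folds
#'
#' Withholds `round(test_frac * n)` points as a seeded random test set; the
#' remaining training points are sorted by longitude and cut into `k`
#' contiguous blocks of near-equal size (regionalised folds).
#'
#' @param occ occurrence data.frame with `lon`.
#' @param test_frac proportion withheld for testing (default 0.25).
#' @param k number of folds on the training part (default 10).
#' @param seed integer seed.
#' @return list `train` (indices), `test` (indices), `fold` (fold label per
#'   training index, aligned with `train`).
#' @export
partition_occurrences <- function(occ, test_frac = 0.25, k = 10, seed = 1) {
  n <- nrow(occ)
  n_test <- round(test_frac * n)
  if (n - n_test < k) stop("too few points for ", k, " folds", call. = FALSE)
  test <- with_seed(seed, sort(sample.int(n, n_test)))
  train <- setdiff(seq_len(n), test)
  ord <- order(occ$lon[train], occ$lat[train])
  sizes <- rep(length(train) %/% k, k)
  extra <- length(train) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  fold <- integer(length(train))
  fold[ord] <- rep(seq_len(k), times = sizes)
  list(train = train, test = test, fold = fold)
}
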