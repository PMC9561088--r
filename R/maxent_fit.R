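# Presence-background maximum-entropy model fitting and projection.
#
# The model is the Gibbs distribution over background cells
#   raw(x) = exp(lambda . f(x)) / Z
# whose coefficients minimize the L1-regularized negative log-likelihood
#   f(lambda) = -mean_pres[lambda.f] + log sum_bg exp(lambda.f)
#               + sum_j beta_j |lambda_j|,
# fitted by cyclic coordinate descent with soft-thresholding (compiled core,
# objective non-increasing by construction).

#' Fit a maximum-entropy niche model on a feature matrix
#'
#' @param features numeric feature matrix over background cells and presence
#'   points (features scaled to \[0,1\] on background; see
#'   [feature_matrix()]).
#' @param presence_idx integer rows of `features` that are presence points.
#' @param bm beta (regularization) multiplier.
#' @param specs feature specification data.frame (from [feature_space()]);
#'   required to derive per-class regularization bounds. If `NULL`, all
#'   features are treated as linear class.
#' @param background_idx rows of `features` forming the background; defaults
#'   to all rows (presence-inclusive background, the usual convention).
#' @param beta optional explicit per-feature bounds overriding the
#'   `bm`/`specs` derivation.
#' @param tol convergence tolerance on the objective per sweep.
#' @param max_sweeps sweep cap.
#' @return A `maxent_model`: coefficients `lambda`, bounds `beta`,
#'   normalizer `logZ`, `entropy` of the fitted distribution, fitted
#'   `objective`, per-update trace (`update_feature`, `update_delta`), and
#'   the presence/background bookkeeping.
#' @export
fit_maxent <- function(features, presence_idx, bm = 1, specs = NULL,
                       background_idx = NULL, beta = NULL, tol = 1e-7,
                       max_sweeps = 500) {
  features <- as.matrix(features)
  stopifnot(length(presence_idx) >= 1,
            all(presence_idx >= 1), all(presence_idx <= nrow(features)))
  if (!all(is.finite(features))) {
    stop("non-finite feature values", call. = FALSE)
  }
  if (is.null(background_idx)) background_idx <- seq_len(nrow(features))
  if (length(background_idx) == 0) {
    stop("no valid background cells", call. = FALSE)
  }
  Fbg <- features[background_idx, , drop = FALSE]
  Fpres <- features[presence_idx, , drop = FALSE]
  if (is.null(beta)) {
    if (is.null(specs)) {
      nms <- colnames(features) %||% paste0("f", seq_len(ncol(features)))
      specs <- data.frame(feature = nms, class = "L", var1 = nms,
                          var2 = NA_character_, stringsAsFactors = FALSE)
    }
    beta <- feature_betas(specs, Fpres, bm = bm)
  }
  stopifnot(length(beta) == ncol(features))
  fit <- .maxent_cd(Fbg, colMeans(Fpres), beta, tol, max_sweeps)
  structure(
    list(lambda = as.numeric(fit$lambda),
         beta = as.numeric(beta),
         logZ = fit$logZ,
         entropy = fit$entropy,
         objective = fit$objective,
         sweep_objective = as.numeric(fit$sweep_objective),
         update_feature = as.integer(fit$update_feature),
         update_delta = as.numeric(fit$update_delta),
         converged = fit$converged,
         n_sweeps = fit$n_sweeps,
         feature_names = colnames(features),
         specs = specs,
         bm = bm,
         n_presence = length(presence_idx),
         n_background = length(background_idx),
         presence_means = colMeans(Fpres)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%d active), m = %d presences, |B| = %d\n",
    length(x$lambda), sum(x$lambda != 0), x$n_presence, x$n_background))
  cat(sprintf("  objective %.6f, entropy %.4f, %d sweeps (%s)\n",
              x$objective, x$entropy, x$n_sweeps,
              if (isTRUE(x$converged)) "converged" else "sweep cap"))
  invisible(x)
}

#' Fit a niche model for one population from a stack and occurrences
#'
#' Builds the feature space on the stack's background cells, evaluates it at
#' the occurrence points, and fits with a presence-inclusive background (the
#' shared study-extent background, making per-population maps directly
#' comparable).
#'
#' @param stack an [env_stack()].
#' @param occ occurrence data.frame with `lon`, `lat`.
#' @param vars variables to use (default: all stack layers).
#' @param fc_set feature classes (string like `"LQH"` or character vector).
#' @param bm beta multiplier.
#' @param n_knots hinge/threshold knots.
#' @param tol,max_sweeps optimizer controls.
#' @return A `maxent_model` with the feature `space` and extraction attached.
#' @export
fit_niche_model <- function(stack, occ, vars = names(stack$layers),
                            fc_set = "H", bm = 1, n_knots = 30,
                            tol = 1e-7, max_sweeps = 500) {
  bg <- background_table(stack)[, vars, drop = FALSE]
  ext <- extract_at(stack, occ)
  keep <- ext$status == "ok"
  if (!any(keep)) stop("no occurrence point falls on valid cells",
                       call. = FALSE)
  pres <- ext[keep, vars, drop = FALSE]
  fs <- feature_space(bg, fc_set, kind = stack$kind[vars], n_knots = n_knots)
  Fbg <- feature_matrix(fs, bg)
  Fpres <- feature_matrix(fs, pres)
  feats <- rbind(Fbg, Fpres)
  model <- fit_maxent(feats,
                      presence_idx = nrow(Fbg) + seq_len(nrow(Fpres)),
                      background_idx = seq_len(nrow(Fbg)),
                      bm = bm, specs = fs$specs, tol = tol,
                      max_sweeps = max_sweeps)
  model$space <- fs
  model$vars <- vars
  model$presence <- pres
  model$n_dropped_occurrences <- sum(!keep)
  model
}

#' Project a fitted model onto an environmental stack
#'
#' The raw output is renormalized to sum to one over the projection grid's
#' valid cells; the logistic output is `raw * e^H / (1 + raw * e^H)` with `H`
#' the training entropy; the cumulative output at a cell is 100 times the
#' total raw mass of cells with raw value less than or equal to that cell's.
#' Values outside the training bounds are clamped (count reported).
#'
#' @param model a model from [fit_niche_model()].
#' @param stack an [env_stack()] covering the model's variables.
#' @return A `suitability_map`: raster_grids `raw`, `logistic`, `cumulative`
#'   plus `clamp_count`.
#' @export
predict_suitability <- function(model, stack) {
  if (is.null(model$space)) {
    stop("model carries no feature space; fit with fit_niche_model()",
         call. = FALSE)
  }
  miss <- setdiff(model$vars, names(stack$layers))
  if (length(miss) > 0) {
    stop("stack is missing model variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bg <- background_table(stack)[, model$vars, drop = FALSE]
  idx <- attr(background_table(stack), "cell_index")
  Fm <- feature_matrix(model$space, bg)
  eta <- as.numeric(Fm %*% model$lambda)
  lse <- logsumexp(eta)
  raw <- exp(eta - lse)
  eH <- exp(model$entropy)
  logistic <- raw * eH / (1 + raw * eH)
  cum <- 100 * cumsum(sort(raw))[rank(raw, ties.method = "max")]
  tmpl <- stack_template(stack)
  as_grid <- function(v) {
    m <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
    m[idx] <- v
    raster_grid(m, tmpl$xll, tmpl$yll, tmpl$cellsize, crs = tmpl$crs)
  }
  structure(list(raw = as_grid(raw), logistic = as_grid(logistic),
                 cumulative = as_grid(cum),
                 clamp_count = attr(Fm, "clamp_count"),
                 entropy = model$entropy),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$raw$values
  cat(sprintf("<suitability_map> %d x %d cells (%d valid), %d clamped\n",
              nrow(v), ncol(v), sum(!is.na(v)), x$clamp_count))
  invisible(x)
}

#' Score covariate rows under a fitted model
#'
#' @param model a model with a feature space.
#' @param table covariate data.frame.
#' @param type `"link"` (eta = lambda.f), `"raw"` (exp(eta - logZ), training
#'   normalizer) or `"logistic"`.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, table,
                           type = c("link", "raw", "logistic")) {
  type <- match.arg(type)
  Fm <- feature_matrix(model$space, table[, model$vars, drop = FALSE])
  eta <- as.numeric(Fm %*% model$lambda)
  if (type == "link") return(eta)
  raw <- exp(eta - model$logZ)
  if (type == "raw") return(raw)
  eH <- exp(model$entropy)
  raw * eH / (1 + raw * eH)
}

#' Training gain of a fitted model
#'
#' Gain is the mean presence log-likelihood improvement over the uniform
#' background baseline, `mean_pres[log raw] + log |B|`; the regularized gain
#' subtracts the L1 penalty. A null model has zero gain.
#'
#' @param model a `maxent_model`.
#' @return list with `gain` and `regularized_gain`.
#' @export
model_gain <- function(model) {
  mean_eta <- sum(model$presence_means * model$lambda)
  gain <- mean_eta - model$logZ + log(model$n_background)
  list(gain = gain,
       regularized_gain = gain - sum(model$beta * abs(model$lambda)))
}
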