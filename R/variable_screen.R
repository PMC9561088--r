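# Covariate screening: normality annotation, Spearman rank correlation with
# the strength bands used in reporting, correlation pruning with an expert
# priority list, PCA inspection, and the iterative maxent-based selection of
# an uncorrelated, high-contribution variable set.

#' Shapiro-Wilk normality annotation per variable
#'
#' Annotates each variable with its W statistic and p-value. The screening
#' itself always uses rank correlation, so this is purely diagnostic; a
#' non-normal covariate set is the expected case.
#'
#' @param table data.frame of covariate samples.
#' @return data.frame `variable, W, p_value, degenerate` (degenerate flags
#'   constant variables, which get NA statistics).
#' @export
normality_check <- function(table) {
  rows <- lapply(names(table), function(v) {
    x <- table[[v]][!is.na(table[[v]])]
    if (length(unique(x)) < 3) {
      return(data.frame(variable = v, W = NA_real_, p_value = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    # shapiro.test caps n at 5000
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    s <- shapiro.test(x)
    data.frame(variable = v, W = unname(s$statistic), p_value = s$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

spearman_strength <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.8, "very strong",
         ifelse(a >= 0.6, "strong",
                ifelse(a >= 0.4, "moderate",
                       ifelse(a >= 0.2, "weak", "very weak"))))
}

#' Spearman rank-correlation report
#'
#' Midrank-tied Spearman correlations for every variable pair, with
#' two-sided p-values and the conventional strength bands (very weak < 0.2
#' <= weak < 0.4 <= moderate < 0.6 <= strong < 0.8 <= very strong).
#'
#' @param table data.frame of covariate rows (>= 3 complete rows).
#' @return list with `r` (correlation matrix), `p` (p-value matrix) and
#'   `strength` (character matrix of band labels).
#' @export
spearman_matrix <- function(table) {
  table <- table[stats::complete.cases(table), , drop = FALSE]
  if (nrow(table) < 3) stop("need at least 3 complete rows", call. = FALSE)
  con <- vapply(table, function(x) length(unique(x)) > 1, logical(1))
  if (!all(con)) {
    stop("constant/all-missing variable(s): ",
         paste(names(table)[!con], collapse = ", "), call. = FALSE)
  }
  p <- ncol(table)
  r <- cor(table, method = "spearman")
  pv <- matrix(0, p, p, dimnames = dimnames(r))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      pv[i, j] <- pv[j, i] <- suppressWarnings(
        cor.test(table[[i]], table[[j]], method = "spearman",
                 exact = FALSE)$p.value)
    }
  }
  list(r = r, p = pv,
       strength = matrix(spearman_strength(r), p, p, dimnames = dimnames(r)))
}

#' Prune correlated variables keeping the highest-priority member
#'
#' Variables are visited in priority order (listed priority first, then the
#' rest alphabetically); a variable is kept iff its absolute Spearman
#' correlation with every already-kept variable is below the threshold. The
#' kept set is therefore pairwise below-threshold, within any correlated
#' group the highest-priority member survives, and the outcome is invariant
#' to the input column order.
#'
#' @param report a correlation report from [spearman_matrix()] (or any list
#'   with an `r` matrix).
#' @param threshold correlation threshold in (0, 1) (default 0.6, the
#'   screening value).
#' @param priority character vector of variable names in decreasing expert
#'   priority; unlisted variables follow in alphabetical order.
#' @return Character vector of kept variable names (visit order).
#' @export
prune_correlated <- function(report, threshold = 0.6, priority = character()) {
  r <- report$r
  stopifnot(threshold > 0, threshold < 1)
  vars <- colnames(r)
  if (length(vars) == 0) stop("empty correlation report", call. = FALSE)
  rest <- sort(setdiff(vars, priority))
  order_v <- c(intersect(priority, vars), rest)
  kept <- character(0)
  for (v in order_v) {
    if (all(abs(r[v, kept]) < threshold)) kept <- c(kept, v)
  }
  kept
}

#' PCA inspection of a covariate table
#'
#' Standardizes variables to zero mean and unit variance (dropping constant
#' variables with a warning) and decomposes; loadings are orthonormal and
#' the variance-explained vector is non-increasing and sums to 100.
#'
#' @param table data.frame of covariate rows.
#' @return list `loadings` (variables x components), `variance_explained`
#'   (percent per component), `scores` (rows x components).
#' @export
pca_summary <- function(table) {
  table <- table[stats::complete.cases(table), , drop = FALSE]
  stopifnot(ncol(table) >= 2, nrow(table) >= 3)
  con <- vapply(table, function(x) length(unique(x)) > 1, logical(1))
  if (!all(con)) {
    warning("dropping constant variable(s): ",
            paste(names(table)[!con], collapse = ", "))
    table <- table[, con, drop = FALSE]
  }
  pc <- prcomp(table, center = TRUE, scale. = TRUE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation, variance_explained = ve, scores = pc$x)
}

#' Iterative maxent-based variable selection
#'
#' For each beta multiplier, repeatedly (1) fits a niche model on the
#' current variable set, (2) drops variables whose percent contribution
#' falls below the threshold, (3) among remaining pairs correlated at or
#' above the threshold over background cells, drops the lower-contribution
#' member, until the set is stable; the stable model's AICc is recorded.
#' The selected set is the variable set of the minimum-AICc stable model.
#'
#' @param stack an [env_stack()].
#' @param occ occurrence data.frame (`lon`, `lat`).
#' @param vars candidate variables (default: all stack layers).
#' @param contrib_threshold minimum percent contribution to survive step (2)
#'   (default 5).
#' @param corr_threshold Spearman threshold for step (3) (default 0.6).
#' @param bm_list beta multipliers to profile (default 1:12).
#' @param fc_set feature classes used during selection (default `"LQH"`).
#' @param n_knots,tol,max_sweeps fitting controls.
#' @param min_occurrences minimum occurrence count (default 15).
#' @return list `selected` (variable names), `score_table`
#'   (bm, n_vars, K, AICc, variables per stable model), `trace`
#'   (per-iteration removals with reasons).
#' @export
mvs_select <- function(stack, occ, vars = names(stack$layers),
                       contrib_threshold = 5, corr_threshold = 0.6,
                       bm_list = 1:12, fc_set = "LQH", n_knots = 10,
                       tol = 1e-7, max_sweeps = 500,
                       min_occurrences = 15) {
  stopifnot(length(vars) >= 2)
  if (nrow(occ) < min_occurrences) {
    stop("need at least ", min_occurrences, " occurrence points",
         call. = FALSE)
  }
  bg <- background_table(stack)
  bg_cont <- bg[, vars[stack$kind[vars] == "continuous"], drop = FALSE]
  rho <- cor(bg_cont, method = "spearman")
  trace <- list()
  note <- function(bm, iter, removed, reason) {
    trace[[length(trace) + 1]] <<- data.frame(
      bm = bm, iteration = iter, removed = removed, reason = reason,
      stringsAsFactors = FALSE)
  }
  score_rows <- list()
  for (bm in bm_list) {
    cur <- vars
    iter <- 0L
    repeat {
      iter <- iter + 1L
      model <- fit_niche_model(stack, occ, vars = cur, fc_set = fc_set,
                               bm = bm, n_knots = n_knots, tol = tol,
                               max_sweeps = max_sweeps)
      contrib <- percent_contribution(model)
      low <- names(contrib)[contrib < contrib_threshold]
      if (length(low) >= length(cur)) {
        # refuse to empty the set: keep the single best contributor
        low <- setdiff(low, names(which.max(contrib)))
      }
      changed <- FALSE
      if (length(low) > 0) {
        for (v in low) note(bm, iter, v, "low-contribution")
        cur <- setdiff(cur, low)
        changed <- TRUE
      }
      # drop the lower-contribution member of correlated pairs
      cc <- intersect(cur, colnames(rho))
      repeat {
        dropped <- FALSE
        cc <- intersect(cur, colnames(rho))
        if (length(cc) >= 2) {
          sub <- abs(rho[cc, cc, drop = FALSE])
          diag(sub) <- 0
          hit <- which(sub >= corr_threshold, arr.ind = TRUE)
          if (nrow(hit) > 0) {
            i <- hit[1, 1]; j <- hit[1, 2]
            pair <- c(cc[i], cc[j])
            loser <- pair[which.min(contrib[pair])]
            note(bm, iter, loser, "correlated-with-better")
            cur <- setdiff(cur, loser)
            changed <- TRUE
            dropped <- TRUE
          }
        }
        if (!dropped) break
      }
      if (!changed) break
      if (length(cur) < 1) {
        stop("all variables eliminated during selection; trace has ",
             length(trace), " removals", call. = FALSE)
      }
    }
    a <- model_aicc(model)
    score_rows[[length(score_rows) + 1]] <- data.frame(
      bm = bm, n_vars = length(cur), K = a$K, AICc = a$AICc,
      valid = a$valid, variables = paste(sort(cur), collapse = ","),
      stringsAsFactors = FALSE)
  }
  score <- do.call(rbind, score_rows)
  ok <- score[score$valid & is.finite(score$AICc), , drop = FALSE]
  if (nrow(ok) == 0) stop("no valid stable model", call. = FALSE)
  best <- ok[order(ok$AICc, ok$K, ok$bm)[1], ]
  list(selected = strsplit(best$variables, ",")[[1]],
       best_bm = best$bm,
       score_table = score,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}
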