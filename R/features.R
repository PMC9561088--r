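# Feature-class transforms of environmental covariates.
#
# Continuous variables are min-max scaled to [0,1] on the background sample;
# feature classes then transform the scaled values: linear (L), quadratic
# (Q), pairwise product (P), threshold (T, step indicators), hinge (H,
# forward and reverse piecewise-linear ramps) and categorical (C, one
# indicator per level). Hinge/threshold knots sit at evenly spaced interior
# quantiles of the background distribution.

FEATURE_CLASSES <- c("L", "Q", "P", "H", "T", "C")

#' Define a feature space over a background sample
#'
#' Records scaling bounds, knots and categorical levels from the background
#' covariate table, so that the identical transform can later be applied to
#' presence points or projection grids (with clamping at the training
#' bounds).
#'
#' @param background data.frame of background covariate rows.
#' @param fc_set character vector, subset of `c("L","Q","P","H","T","C")`.
#'   May also be given as a single string like `"LQH"`.
#' @param kind named character vector (`"continuous"`/`"categorical"` per
#'   column); defaults to all-continuous.
#' @param n_knots number of interior quantile knots for hinge and threshold
#'   features (default 30).
#' @return A `feature_space` object; its `specs` data.frame has one row per
#'   feature (`feature, class, var1, var2, knot, level`).
#' @export
feature_space <- function(background, fc_set, kind = NULL, n_knots = 30) {
  fc_set <- parse_fc(fc_set)
  vars <- names(background)
  if (is.null(kind)) kind <- setNames(rep("continuous", length(vars)), vars)
  stopifnot(all(vars %in% names(kind)))
  cont <- vars[kind[vars] == "continuous"]
  cat_v <- vars[kind[vars] == "categorical"]
  # categorical layers always carry their indicator features
  if (length(cat_v) > 0 && !("C" %in% fc_set)) fc_set <- c(fc_set, "C")

  bounds <- lapply(setNames(cont, cont), function(v) {
    x <- background[[v]]
    c(min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  })
  probs <- seq_len(n_knots) / (n_knots + 1)
  knots <- lapply(setNames(cont, cont), function(v) {
    b <- bounds[[v]]
    if (b["max"] <= b["min"]) return(numeric(0))
    k <- unique(as.numeric(quantile(background[[v]], probs, na.rm = TRUE,
                                    names = FALSE)))
    k[k > b["min"] & k < b["max"]]
  })
  levels_ <- lapply(setNames(cat_v, cat_v), function(v) {
    sort(unique(background[[v]]))
  })

  specs <- list()
  add <- function(feature, class, var1, var2 = NA, knot = NA, level = NA) {
    specs[[length(specs) + 1]] <<- data.frame(
      feature = feature, class = class, var1 = var1, var2 = var2,
      knot = knot, level = level, stringsAsFactors = FALSE)
  }
  for (v in cont) {
    if ("L" %in% fc_set) add(paste0("L_", v), "L", v)
    if ("Q" %in% fc_set) add(paste0("Q_", v), "Q", v)
    if ("T" %in% fc_set) {
      for (k in knots[[v]]) {
        add(sprintf("T_%s_%.8g", v, k), "T", v, knot = k)
      }
    }
    if ("H" %in% fc_set) {
      for (k in knots[[v]]) {
        add(sprintf("Hf_%s_%.8g", v, k), "H", v, knot = k)
        add(sprintf("Hr_%s_%.8g", v, k), "H", v, knot = -k)
      }
    }
  }
  if ("P" %in% fc_set && length(cont) >= 2) {
    pairs <- utils::combn(cont, 2)
    for (i in seq_len(ncol(pairs))) {
      add(paste0("P_", pairs[1, i], "_x_", pairs[2, i]), "P",
          pairs[1, i], pairs[2, i])
    }
  }
  for (v in cat_v) {
    for (lv in levels_[[v]]) {
      add(sprintf("C_%s_%s", v, lv), "C", v, level = lv)
    }
  }
  specs <- do.call(rbind, specs)
  if (is.null(specs) || nrow(specs) == 0) {
    stop("empty feature set: no features for fc_set {",
         paste(fc_set, collapse = ","), "}", call. = FALSE)
  }
  structure(list(specs = specs, bounds = bounds, knots = knots,
                 levels = levels_, fc_set = fc_set, vars = vars,
                 kind = kind[vars]),
            class = "feature_space")
}

parse_fc <- function(fc_set) {
  if (length(fc_set) == 1 && nchar(fc_set) > 1) {
    fc_set <- strsplit(fc_set, "")[[1]]
  }
  fc_set <- toupper(fc_set)
  if (length(fc_set) == 0) stop("fc_set is empty", call. = FALSE)
  bad <- setdiff(fc_set, FEATURE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown feature class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unique(fc_set)
}

# Hinge spec convention: positive knot = forward hinge, negative = reverse
# (the reverse knot value is abs(knot)).

#' Evaluate a feature space on covariate rows
#'
#' Continuous values are min-max scaled with the training background bounds;
#' values outside the bounds are clamped into \[0,1\] and counted.
#'
#' @param fspace a [feature_space()].
#' @param table data.frame of covariate rows (must contain all variables).
#' @return Numeric matrix (rows x features) with attribute `clamp_count`.
#' @export
feature_matrix <- function(fspace, table) {
  miss <- setdiff(fspace$vars, names(table))
  if (length(miss) > 0) {
    stop("covariate table is missing variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  clamp_count <- 0L
  scaled <- lapply(setNames(fspace$vars, fspace$vars), function(v) {
    if (fspace$kind[[v]] == "categorical") return(table[[v]])
    b <- fspace$bounds[[v]]
    rng <- b["max"] - b["min"]
    if (rng <= 0) return(rep(0.5, n))
    s <- (table[[v]] - b["min"]) / rng
    clamp_count <<- clamp_count + sum(s < 0 | s > 1, na.rm = TRUE)
    pmin(pmax(s, 0), 1)
  })
  sp <- fspace$specs
  cols <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    cl <- sp$class[i]; v <- sp$var1[i]
    cols[[i]] <- switch(
      cl,
      L = scaled[[v]],
      Q = scaled[[v]]^2,
      P = scaled[[v]] * scaled[[sp$var2[i]]],
      T = as.numeric(table[[v]] > sp$knot[i]),
      H = {
        b <- fspace$bounds[[v]]
        k <- sp$knot[i]
        if (k > 0) {
          pmin(pmax((table[[v]] - k) / (b["max"] - k), 0), 1)
        } else {
          k <- -k
          pmin(pmax((k - table[[v]]) / (k - b["min"]), 0), 1)
        }
      },
      C = as.numeric(table[[v]] == sp$level[i]),
      stop("unhandled feature class ", cl))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- sp$feature
  attr(m, "clamp_count") <- clamp_count
  m
}

#' Build the background feature matrix and feature specifications
#'
#' Convenience wrapper: defines the feature space on the background table and
#' evaluates it there.
#'
#' @inheritParams feature_space
#' @return list with elements `features` (matrix) and `space`
#'   (the [feature_space()]).
#' @export
build_features <- function(background, fc_set, kind = NULL, n_knots = 30) {
  fs <- feature_space(background, fc_set, kind = kind, n_knots = n_knots)
  list(features = feature_matrix(fs, background), space = fs)
}

# Published per-class default regularization base constants, piecewise-linear
# in the presence sample size m and flat outside the tabulated range.
reg_constant <- function(class, m) {
  tab <- switch(class,
                L = , Q = , P = list(x = c(0, 10, 17, 30),
                                     y = c(2.6, 1.6, 0.5, 0.05)),
                H = list(x = c(0, 1), y = c(0.5, 0.5)),
                T = list(x = c(0, 100), y = c(2, 1)),
                C = list(x = c(0, 10, 17), y = c(0.65, 0.5, 0.25)),
                stop("unhandled feature class ", class))
  stats::approx(tab$x, tab$y, xout = m, rule = 2)$y
}

#' Per-feature L1 bounds
#'
#' `beta_j = BM * c_class(m) * s_j / sqrt(m)` where `m` is the presence
#' count, `s_j` the presence-sample standard deviation of feature j (floored
#' at 0.001 on the \[0,1\] feature scale so degenerate features stay bounded)
#' and `c_class(m)` the published per-class base constant.
#'
#' @param specs feature specification data.frame from [feature_space()].
#' @param F_pres presence feature matrix.
#' @param bm beta multiplier (default 1).
#' @return Numeric vector of per-feature regularization bounds.
#' @export
feature_betas <- function(specs, F_pres, bm = 1) {
  m <- nrow(F_pres)
  s <- apply(F_pres, 2, sd)
  if (m <= 1) s[] <- 1
  s <- pmax(s, 0.001)
  cc <- vapply(specs$class, reg_constant, numeric(1), m = m)
  as.numeric(bm * cc * s / sqrt(m))
}
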