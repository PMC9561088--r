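# End-to-end orchestration of the ecotype-delineation protocol:
# load stack -> expand occurrences -> screen variables (correlation, PCA,
# iterative maxent selection) -> tune feature class and beta multiplier by
# AICc -> pooled and per-district models -> evaluation -> similarity
# matrices under both metrics -> clustering with linkage selection ->
# ecotype assignment and combined maps. Every stage's artefacts are written
# under one run directory and a machine-readable report summarizes the run.

#' Build a run configuration
#'
#' All knobs of the protocol in one list; unspecified entries take the
#' defaults below. `stack` and `sampling_table` may be given as paths (layer
#' manifest CSV / sampling CSV) or as in-memory objects.
#'
#' @param stack an [env_stack()] or a layer-manifest path.
#' @param sampling_table a `sampling_table` or a CSV path.
#' @param seed global integer seed.
#' @param out_dir output directory (`NULL` for no artefacts).
#' @param ... overrides of the default settings: `corr_threshold` (0.6),
#'   `contrib_threshold` (5), `priority` (expert priority list for
#'   correlation pruning), `mvs_fc_set` ("LQH"), `mvs_bm_list` (c(1,2,4)),
#'   `fc_sets`, `bm_list` (tuning grid), `n_knots` (8), `test_frac` (0.25),
#'   `k_folds` (10), `k_range` (2:6), `k_override` (NULL),
#'   `overlap_surface` ("logistic"), `write_maps` (TRUE), `n_extra` (9),
#'   `area_km2` (1.2), `min_occurrences` (15).
#' @return A `run_config` list.
#' @export
run_config <- function(stack, sampling_table, seed = 1, out_dir = NULL,
                       ...) {
  cfg <- list(
    stack = stack, sampling_table = sampling_table, seed = seed,
    out_dir = out_dir,
    n_extra = 9, area_km2 = 1.2,
    corr_threshold = 0.6, contrib_threshold = 5, priority = character(),
    mvs_fc_set = "LQH", mvs_bm_list = c(1, 2, 4), min_occurrences = 15,
    fc_sets = c("L", "LQ", "LQP"), bm_list = c(1, 2, 4),
    n_knots = 8, test_frac = 0.25, k_folds = 10,
    k_range = 2:6, k_override = NULL,
    overlap_surface = "logistic", write_maps = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown configuration entr", if (length(bad) > 1) "ies: " else
      "y: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Paths in the file resolve relative to the file's directory.
#'
#' @param path YAML file with at least `stack` and `sampling_table` entries.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$stack), !is.null(y$sampling_table))
  dir <- dirname(path)
  fix <- function(p) {
    if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(dir, p)
    else p
  }
  y$stack <- fix(y$stack)
  y$sampling_table <- fix(y$sampling_table)
  args <- y[setdiff(names(y), c("stack", "sampling_table"))]
  do.call(run_config, c(list(stack = y$stack,
                             sampling_table = y$sampling_table), args))
}

resolve_inputs <- function(config) {
  stack <- config$stack
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "env_stack"))
  tab <- config$sampling_table
  if (is.character(tab)) tab <- parse_sampling_table(tab)
  list(stack = stack, table = tab)
}

save_artifact <- function(out_dir, name, writer) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writer(file.path(out_dir, name))
  invisible(name)
}

#' Run the full ecotype-delineation pipeline
#'
#' Executes every protocol stage in order and writes the stage artefacts
#' (occurrence CSV, correlation matrix, selection trace, tuning grid,
#' per-district evaluation, similarity matrices, Newick dendrograms,
#' assignment CSV, optional suitability and ecotype maps) plus a JSON
#' report under `config$out_dir`. The report carries every seed, threshold
#' and chosen parameter; rerunning with an identical configuration
#' reproduces it byte for byte.
#'
#' @param config a [run_config()].
#' @return The run report (list), invisibly also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- resolve_inputs(config)
  stack <- inp$stack; table <- inp$table
  out <- config$out_dir
  seed <- config$seed

  # -- occurrences ---------------------------------------------------------
  occs <- expand_all_districts(table, n_extra = config$n_extra,
                               area_km2 = config$area_km2, seed = seed)
  pooled <- do.call(rbind, occs)
  rownames(pooled) <- NULL
  save_artifact(out, "occurrences.csv", function(p) {
    utils::write.csv(pooled, p, row.names = FALSE)
  })

  # -- screening -----------------------------------------------------------
  bg <- background_table(stack)
  cont <- names(stack$layers)[stack$kind == "continuous"]
  normality <- normality_check(bg[cont])
  corr <- spearman_matrix(bg[cont])
  kept_corr <- prune_correlated(corr, threshold = config$corr_threshold,
                                priority = config$priority)
  pca <- pca_summary(bg[cont])
  mvs <- mvs_select(stack, pooled,
                    contrib_threshold = config$contrib_threshold,
                    corr_threshold = config$corr_threshold,
                    bm_list = config$mvs_bm_list,
                    fc_set = config$mvs_fc_set,
                    n_knots = config$n_knots,
                    min_occurrences = config$min_occurrences)
  selected <- sort(mvs$selected)
  save_artifact(out, "spearman_matrix.csv", function(p) {
    utils::write.csv(corr$r, p)
  })
  save_artifact(out, "selection_trace.json", function(p) {
    jsonlite::write_json(list(score_table = mvs$score_table,
                              trace = mvs$trace, selected = selected),
                         p, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  })

  # -- tuning --------------------------------------------------------------
  part <- partition_occurrences(pooled, test_frac = config$test_frac,
                                k = config$k_folds,
                                seed = stable_seed(seed, "partition"))
  train <- pooled[part$train, , drop = FALSE]
  test <- pooled[part$test, , drop = FALSE]
  grid <- enumerate_grid(config$fc_sets, config$bm_list)
  tuned <- tune_grid(stack, train, selected, grid,
                     n_knots = config$n_knots)
  best <- select_best(tuned)
  save_artifact(out, "tuning_grid.csv", function(p) {
    utils::write.csv(tuned, p, row.names = FALSE)
  })

  # -- pooled model and evaluation ----------------------------------------
  pooled_model <- fit_niche_model(stack, train, vars = selected,
                                  fc_set = best$fc_set, bm = best$bm,
                                  n_knots = config$n_knots)
  pooled_eval <- evaluate_model(pooled_model, stack, test)
  contrib <- percent_contribution(pooled_model)
  perm <- permutation_importance(pooled_model, stack,
                                 seed = stable_seed(seed, "permimp"))
  cv_auc <- vapply(seq_len(config$k_folds), function(f) {
    tr <- train[part$fold != f, , drop = FALSE]
    ho <- train[part$fold == f, , drop = FALSE]
    m <- fit_niche_model(stack, tr, vars = selected, fc_set = best$fc_set,
                         bm = best$bm, n_knots = config$n_knots)
    evaluate_model(m, stack, ho)$auc_test
  }, numeric(1))
  jack <- if (length(selected) >= 2) {
    jackknife_importance(stack, train, selected, test_occ = test,
                         fc_set = best$fc_set, bm = best$bm,
                         n_knots = config$n_knots)
  } else NULL
  curves <- do.call(rbind, lapply(selected, function(v) {
    response_curve(pooled_model, stack, v)
  }))
  save_artifact(out, "response_curves.csv", function(p) {
    utils::write.csv(curves, p, row.names = FALSE)
  })
  if (!is.null(jack)) {
    save_artifact(out, "jackknife.csv", function(p) {
      utils::write.csv(jack$table, p, row.names = FALSE)
    })
  }

  # -- per-district models -------------------------------------------------
  maps <- list(); district_auc <- c()
  for (d in names(occs)) {
    m <- fit_niche_model(stack, occs[[d]], vars = selected,
                         fc_set = best$fc_set, bm = best$bm,
                         n_knots = config$n_knots)
    maps[[d]] <- predict_suitability(m, stack)
    district_auc[d] <- evaluate_model(m, stack)$auc_train
  }
  if (isTRUE(config$write_maps) && !is.null(out)) {
    dir.create(file.path(out, "maps"), showWarnings = FALSE,
               recursive = TRUE)
    for (d in names(maps)) {
      write_grid(maps[[d]]$cumulative,
                 file.path(out, "maps", paste0(d, "_cumulative.asc")))
    }
  }

  # -- similarity and clustering under both metrics ------------------------
  metrics <- c("pearson_r", "overlap_I")
  sim <- list(); clus <- list(); assign_tab <- list()
  for (metric in metrics) {
    S <- if (metric == "overlap_I" &&
             identical(config$overlap_surface, "logistic")) {
      similarity_matrix(lapply(maps, function(m) m$logistic), metric)
    } else {
      similarity_matrix(maps, metric)
    }
    D <- row_distance(S)
    cl <- compare_linkages(D)
    tree <- cl$trees[[cl$chosen]]
    k <- choose_k(tree, D, k_range = config$k_range,
                  override = config$k_override)
    assignment <- cut_assign(tree, k)
    sim[[metric]] <- S
    clus[[metric]] <- list(ac = as.list(cl$ac), chosen_linkage = cl$chosen,
                           k = k, assignment = as.list(assignment))
    assign_tab[[metric]] <- data.frame(
      population = names(assignment), ecotype = unname(assignment),
      metric = metric, stringsAsFactors = FALSE)
    save_artifact(out, paste0("similarity_", metric, ".csv"), function(p) {
      utils::write.csv(unclass(S), p)
    })
    save_artifact(out, paste0("dendrogram_", metric, ".nwk"), function(p) {
      write_tree_newick(tree, p)
    })
    if (isTRUE(config$write_maps) && !is.null(out)) {
      em <- ecotype_maps(maps, assignment)
      for (e in names(em)) {
        write_grid(em[[e]], file.path(out, "maps",
                                      paste0(metric, "_", e, ".asc")))
      }
    }
  }
  save_artifact(out, "assignments.csv", function(p) {
    utils::write.csv(do.call(rbind, assign_tab), p, row.names = FALSE)
  })

  # populations whose cluster differs between the two metrics (after
  # best-label matching, a population is flagged when its co-membership
  # pattern differs)
  a1 <- unlist(clus[["pearson_r"]]$assignment)
  a2 <- unlist(clus[["overlap_I"]]$assignment)
  pops <- names(occs)
  disagree <- vapply(pops, function(p) {
    !identical(a1[pops] == a1[[p]], a2[pops] == a2[[p]])
  }, logical(1))

  report <- list(
    config = list(
      seed = seed, n_extra = config$n_extra, area_km2 = config$area_km2,
      corr_threshold = config$corr_threshold,
      contrib_threshold = config$contrib_threshold,
      mvs_fc_set = config$mvs_fc_set, mvs_bm_list = config$mvs_bm_list,
      fc_sets = config$fc_sets, bm_list = config$bm_list,
      n_knots = config$n_knots, test_frac = config$test_frac,
      k_folds = config$k_folds, k_range = config$k_range,
      k_override = config$k_override,
      overlap_surface = config$overlap_surface,
      partition_seed = stable_seed(seed, "partition")),
    design = list(n_districts = length(occs),
                  n_villages = nrow(table),
                  n_points = nrow(pooled)),
    screening = list(
      n_variables = length(stack$layers),
      normality = normality,
      corr_kept = kept_corr,
      pca_variance_explained = pca$variance_explained,
      selected = selected,
      mvs_best_bm = mvs$best_bm),
    tuning = list(n_candidates = nrow(grid), fc_set = best$fc_set,
                  bm = best$bm, AICc = best$AICc, K = best$K),
    pooled_model = list(
      auc_train = pooled_eval$auc_train, auc_test = pooled_eval$auc_test,
      gain_train = pooled_eval$gain_train,
      cv_auc = cv_auc,
      percent_contribution = as.list(contrib),
      permutation_importance = as.list(perm)),
    districts = list(auc_train = as.list(district_auc)),
    clustering = clus,
    cross_metric_disagreement = names(disagree)[disagree])
  save_artifact(out, "report.json", function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  })
  invisible(report)
}
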