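# Synthetic landscape generator: correlated, spatially smooth environmental
# layers with planted ecotype suitability surfaces and a matching
# village-sampling design, so the entire protocol runs and can be validated
# offline against a known truth.

#' Specify a synthetic landscape
#'
#' Continuous layers are built by Gaussian-blurring independent white-noise
#' fields (spatial smoothness), standardizing them, and mixing across layers
#' through the Cholesky factor of the target correlation matrix; each layer
#' is then placed on its nominal scale via `means`/`sds`. An optional
#' categorical layer is a quantile-binned smoothed field.
#'
#' @param nrow,ncol grid size in cells.
#' @param corr target cross-layer correlation matrix (symmetric PSD, unit
#'   diagonal) with dimnames naming the layers.
#' @param means,sds nominal per-layer mean and spread (named as `corr`).
#' @param groups named group labels per layer.
#' @param blur_sigma Gaussian blur standard deviation in cells.
#' @param categorical `NULL`, or list `name, levels, group` for one
#'   categorical layer.
#' @param cellsize,xll,yll grid placement in degrees.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(nrow = 64, ncol = 64, corr, means, sds,
                           groups, blur_sigma = 5, categorical = NULL,
                           cellsize = 0.00898, xll = 38.0, yll = 13.0) {
  stopifnot(isSymmetric(unname(corr)), all(abs(diag(corr) - 1) < 1e-12))
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  nm <- colnames(corr)
  stopifnot(!is.null(nm), all(nm %in% names(means)), all(nm %in% names(sds)),
            all(nm %in% names(groups)))
  structure(list(nrow = nrow, ncol = ncol, corr = corr, means = means[nm],
                 sds = sds[nm], groups = groups, blur_sigma = blur_sigma,
                 categorical = categorical, cellsize = cellsize,
                 xll = xll, yll = yll),
            class = "landscape_spec")
}

# separable Gaussian blur with reflected edges
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    pad <- c(x[half:1], x, x[n:(n - half + 1)])
    as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + n)]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Generate the synthetic environmental stack
#'
#' Deterministic for a fixed seed.
#'
#' @param spec a [landscape_spec()].
#' @param seed integer seed.
#' @return An [env_stack()].
#' @export
gen_layers <- function(spec, seed = 1) {
  nm <- colnames(spec$corr)
  d <- length(nm)
  ncell <- spec$nrow * spec$ncol
  with_seed(seed, {
    Z <- vapply(seq_len(d), function(i) {
      f <- gaussian_blur(matrix(rnorm(ncell), spec$nrow, spec$ncol),
                         spec$blur_sigma)
      as.numeric(scale(as.numeric(f)))
    }, numeric(ncell))
    L <- t(chol(spec$corr))
    X <- Z %*% t(L)
    layers <- lapply(seq_len(d), function(i) {
      v <- spec$means[[nm[i]]] + spec$sds[[nm[i]]] * X[, i]
      raster_grid(matrix(v, spec$nrow, spec$ncol), spec$xll, spec$yll,
                  spec$cellsize)
    })
    names(layers) <- nm
    kind <- setNames(rep("continuous", d), nm)
    groups <- spec$groups[nm]
    if (!is.null(spec$categorical)) {
      ct <- spec$categorical
      f <- gaussian_blur(matrix(rnorm(ncell), spec$nrow, spec$ncol),
                         ct$blur_sigma %||% spec$blur_sigma)
      cuts <- quantile(f, probs = seq(0, 1, length.out = ct$levels + 1))
      cuts[1] <- -Inf; cuts[ct$levels + 1] <- Inf
      cv <- as.numeric(cut(as.numeric(f), breaks = cuts, labels = FALSE))
      layers[[ct$name]] <- raster_grid(
        matrix(cv, spec$nrow, spec$ncol), spec$xll, spec$yll, spec$cellsize)
      kind[ct$name] <- "categorical"
      groups[ct$name] <- ct$group %||% "vegetation_landcover"
    }
    env_stack(layers, groups = groups, kind = kind)
  })
}

#' Planted ecotype truth
#'
#' @param optima K x d matrix of environmental optima (rows = ecotypes,
#'   columns = driver layers, in layer units) with distinct rows.
#' @param widths K x d matrix of positive niche widths (same shape).
#' @return An `ecotype_truth` list.
#' @export
ecotype_truth <- function(optima, widths) {
  stopifnot(all(dim(optima) == dim(widths)), all(widths > 0),
            !is.null(colnames(optima)),
            !anyDuplicated(apply(optima, 1, paste, collapse = "/")))
  structure(list(optima = optima, widths = widths,
                 drivers = colnames(optima), K = nrow(optima)),
            class = "ecotype_truth")
}

#' Planted suitability surfaces
#'
#' Per ecotype, the product over driver layers of Gaussian responses
#' `exp(-(v - opt)^2 / (2 w^2))`, normalized to a maximum of one.
#'
#' @param stack an [env_stack()] containing the driver layers.
#' @param truth an [ecotype_truth()].
#' @return Named list of raster_grids (`ecotype_1` ... `ecotype_K`).
#' @export
plant_suitability <- function(stack, truth) {
  miss <- setdiff(truth$drivers, names(stack$layers))
  if (length(miss) > 0) {
    stop("missing driver layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tmpl <- stack_template(stack)
  out <- lapply(seq_len(truth$K), function(k) {
    logs <- 0
    for (d in truth$drivers) {
      v <- stack$layers[[d]]$values
      logs <- logs - (v - truth$optima[k, d])^2 / (2 * truth$widths[k, d]^2)
    }
    s <- exp(logs)
    s[!stack$mask] <- NA
    s <- s / max(s, na.rm = TRUE)
    raster_grid(s, tmpl$xll, tmpl$yll, tmpl$cellsize)
  })
  names(out) <- paste0("ecotype_", seq_len(truth$K))
  out
}

#' Sample a village study design from planted suitability
#'
#' Village centres are drawn (without replacement within a district) with
#' probability proportional to the generating ecotype's true suitability;
#' districts are labelled with their ecotype only in the returned truth
#' table, which the analysis never sees. Altitudes are drawn from
#' ecotype-specific bands and labelled by [classify_altitude()]. Occurrence
#' expansion then follows the standard village protocol.
#'
#' @param truths per-ecotype suitability grids from [plant_suitability()].
#' @param n_districts_per_ecotype districts per ecotype (default 4).
#' @param villages_per_district villages in each district (default 2).
#' @param altitude_bands list of `c(lo, hi)` metres per ecotype.
#' @param n_extra,area_km2 occurrence expansion settings.
#' @param seed integer seed.
#' @return list `table` (a `sampling_table`), `truth` (data.frame district,
#'   ecotype), `occurrences` (per-district point sets).
#' @export
sample_study <- function(truths, n_districts_per_ecotype = 4,
                         villages_per_district = 2,
                         altitude_bands = NULL, n_extra = 9, area_km2 = 1.2,
                         seed = 1) {
  K <- length(truths)
  if (is.null(altitude_bands)) {
    altitude_bands <- lapply(seq_len(K), function(k) {
      c(500, 2900) + (k - 1) * 0
    })
    altitude_bands <- list(c(600, 1400), c(900, 1500), c(1600, 2200),
                           c(2300, 2900))[seq_len(K)]
  }
  rows <- list()
  truth_rows <- list()
  d_id <- 0L
  for (k in seq_len(K)) {
    g <- truths[[k]]
    w <- as.numeric(g$values)
    ok <- which(!is.na(w) & w > 0)
    if (length(ok) < villages_per_district * n_districts_per_ecotype) {
      stop("degenerate truth surface for ecotype ", k, call. = FALSE)
    }
    for (d in seq_len(n_districts_per_ecotype)) {
      d_id <- d_id + 1L
      district <- sprintf("District_%02d", d_id)
      dseed <- stable_seed(seed, paste0("sample/", district))
      cells <- with_seed(dseed, {
        sample(ok, villages_per_district, prob = w[ok])
      })
      rc <- arrayInd(cells, dim(g$values))
      ctr <- cell_center(g, rc[, 1], rc[, 2])
      alts <- with_seed(dseed + 1L, {
        round(runif(villages_per_district, altitude_bands[[k]][1],
                    altitude_bands[[k]][2]))
      })
      rows[[d_id]] <- data.frame(
        district = district,
        village = sprintf("%s_V%d", district, seq_len(villages_per_district)),
        latitude = ctr$y, longitude = ctr$x, altitude = alts,
        agroecology = classify_altitude(alts), stringsAsFactors = FALSE)
      truth_rows[[d_id]] <- data.frame(district = district, ecotype = k,
                                       stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  class(table) <- c("sampling_table", "data.frame")
  occ <- expand_all_districts(table, n_extra = n_extra, area_km2 = area_km2,
                              seed = seed)
  list(table = table, truth = do.call(rbind, truth_rows), occurrences = occ)
}

#' The packaged synthetic study scenario
#'
#' The default desk-scale scenario mirroring the study design: a 64 x 64
#' one-kilometre grid with seven continuous layers (three climatic drivers,
#' two distractors correlated with the drivers, two independent noise
#' decoys) and one categorical layer; four planted ecotypes with
#' well-separated optima (three widths apart per differing driver); sixteen
#' districts of two villages, expanded to ten occurrence points per village
#' (320 points in total).
#'
#' @param seed integer seed driving every stochastic step.
#' @return list `spec, stack, truth, suitability, design` (the latter from
#'   [sample_study()]).
#' @export
synthetic_scenario <- function(seed = 1) {
  nm <- c("bio5", "bio8", "bio13", "bio4", "bio12", "soil_clay",
          "grass_land")
  corr <- diag(7)
  dimnames(corr) <- list(nm, nm)
  corr["bio5", "bio8"] <- corr["bio8", "bio5"] <- 0.2
  corr["bio5", "bio13"] <- corr["bio13", "bio5"] <- 0.2
  corr["bio8", "bio13"] <- corr["bio13", "bio8"] <- 0.2
  # four distractors, each strongly correlated with one driver and
  # weakly with the others (collinearity mirrors real climate stacks)
  tie <- function(a, b, r) corr[a, b] <<- corr[b, a] <<- r
  tie("bio4", "bio5", 0.85); tie("bio4", "bio8", 0.17)
  tie("bio4", "bio13", 0.17)
  tie("bio12", "bio13", 0.85); tie("bio12", "bio5", 0.17)
  tie("bio12", "bio8", 0.17)
  tie("soil_clay", "bio8", 0.85); tie("soil_clay", "bio5", 0.17)
  tie("soil_clay", "bio13", 0.17); tie("soil_clay", "bio4", 0.14)
  tie("soil_clay", "bio12", 0.14)
  tie("grass_land", "bio5", 0.7); tie("grass_land", "bio8", 0.14)
  tie("grass_land", "bio13", 0.14); tie("grass_land", "bio4", 0.6)
  tie("grass_land", "bio12", 0.12)
  means <- c(bio5 = 30, bio8 = 20, bio13 = 60, bio4 = 150, bio12 = 600,
             soil_clay = 30, grass_land = 20)
  sds <- c(bio5 = 4, bio8 = 3, bio13 = 25, bio4 = 30, bio12 = 150,
           soil_clay = 8, grass_land = 10)
  groups <- c(bio5 = "climatic", bio8 = "climatic", bio13 = "climatic",
              bio4 = "climatic", bio12 = "climatic", soil_clay = "soil",
              grass_land = "vegetation_landcover",
              crop_dominance = "vegetation_landcover")
  spec <- landscape_spec(
    nrow = 64, ncol = 64, corr = corr, means = means, sds = sds,
    groups = groups, blur_sigma = 1.5,
    categorical = list(name = "crop_dominance", levels = 2,
                       group = "vegetation_landcover", blur_sigma = 0.75))
  stack <- gen_layers(spec, seed = seed)
  drivers <- c("bio5", "bio8", "bio13")
  # optima at +-1.2 standardized units, width 0.5 sd: differing coordinates
  # are 2.4 sd = 4.8 niche widths apart (well-separated)
  std_opt <- rbind(c(-1.2, -1.2, -1.2),
                   c(-1.2,  1.2,  1.2),
                   c( 1.2, -1.2,  1.2),
                   c( 1.2,  1.2, -1.2))
  colnames(std_opt) <- drivers
  optima <- sweep(sweep(std_opt, 2, sds[drivers], `*`), 2, means[drivers],
                  `+`)
  widths <- matrix(rep(0.5 * sds[drivers], each = 4), 4, 3,
                   dimnames = list(NULL, drivers))
  truth <- ecotype_truth(optima, widths)
  suit <- plant_suitability(stack, truth)
  design <- sample_study(suit, n_districts_per_ecotype = 4,
                         villages_per_district = 2,
                         seed = stable_seed(seed, "study-design"))
  list(spec = spec, stack = stack, truth = truth, suitability = suit,
       design = design)
}
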