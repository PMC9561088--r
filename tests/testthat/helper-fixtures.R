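# Small fixtures built in code: hand-sized grids, stacks and scenarios.

make_grid <- function(values, xll = 38, yll = 13, cellsize = 0.01) {
  raster_grid(values, xll = xll, yll = yll, cellsize = cellsize)
}

# 4x4 two-layer stack with known cell values (value = 10*row + col for
# layer a; row index for layer b), one masked cell in layer b
tiny_stack <- function() {
  a <- outer(1:4, 1:4, function(r, c) 10 * r + c)
  b <- matrix(rep(1:4, 4), 4, 4)
  b[2, 3] <- NA
  env_stack(list(a = make_grid(a), b = make_grid(b)),
            groups = c(a = "climatic", b = "soil"),
            kind = c(a = "continuous", b = "continuous"))
}

# a feature matrix toy: n background cells, 2 features, fixed presences
toy_problem <- function(n = 20, seed = 42) {
  set.seed(seed)
  feats <- cbind(f1 = runif(n), f2 = runif(n)^2)
  list(features = feats, presence = c(1L, 4L, 8L, 15L))
}

# brute-force L1 maxent solver: box-constrained quasi-Newton on the
# positive/negative split of lambda (independent of the coordinate-descent
# path)
oracle_maxent <- function(features, presence_idx, beta) {
  p <- ncol(features)
  pbar <- colMeans(features[presence_idx, , drop = FALSE])
  obj <- function(t) {
    l <- t[seq_len(p)] - t[p + seq_len(p)]
    eta <- as.numeric(features %*% l)
    -sum(pbar * l) + log(sum(exp(eta))) + sum(beta * (t[seq_len(p)] +
                                                        t[p + seq_len(p)]))
  }
  o <- stats::optim(rep(0, 2 * p), obj, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 20000, factr = 1))
  list(lambda = o$par[seq_len(p)] - o$par[p + seq_len(p)],
       objective = o$value)
}

# small landscape with one true driver, a duplicate of it, and pure noise;
# occurrences sampled from a planted Gaussian response on the driver
planted_mini <- function(seed = 7, nrow = 32, ncol = 32) {
  corr <- diag(3)
  dimnames(corr) <- list(c("driver", "twin", "noise"),
                         c("driver", "twin", "noise"))
  corr["driver", "twin"] <- corr["twin", "driver"] <- 0.97
  spec <- landscape_spec(
    nrow = nrow, ncol = ncol, corr = corr,
    means = c(driver = 0, twin = 0, noise = 0),
    sds = c(driver = 1, twin = 1, noise = 1),
    groups = c(driver = "climatic", twin = "climatic", noise = "soil"),
    blur_sigma = 1.5)
  stack <- gen_layers(spec, seed = seed)
  truth <- ecotype_truth(
    optima = matrix(1.2, 1, 1, dimnames = list(NULL, "driver")),
    widths = matrix(0.5, 1, 1, dimnames = list(NULL, "driver")))
  suit <- plant_suitability(stack, truth)[[1]]
  w <- as.numeric(suit$values)
  cells <- with_seed(seed + 1, sample(which(!is.na(w)), 40, prob = w))
  rc <- arrayInd(cells, dim(suit$values))
  ctr <- cell_center(suit, rc[, 1], rc[, 2])
  occ <- data.frame(lon = ctr$x, lat = ctr$y)
  list(stack = stack, occ = occ, suit = suit)
}

# tiny two-ecotype scenario for fast pipeline runs
mini_scenario <- function(seed = 3) {
  nm <- c("t1", "t2", "d1")
  corr <- diag(3); dimnames(corr) <- list(nm, nm)
  corr["d1", "t1"] <- corr["t1", "d1"] <- 0.85
  spec <- landscape_spec(
    nrow = 28, ncol = 28, corr = corr,
    means = c(t1 = 20, t2 = 50, d1 = 5), sds = c(t1 = 4, t2 = 10, d1 = 1),
    groups = c(t1 = "climatic", t2 = "climatic", d1 = "soil"),
    blur_sigma = 1.5)
  stack <- gen_layers(spec, seed = seed)
  optima <- rbind(c(20 - 4 * 1.2, 50 + 10 * 1.2),
                  c(20 + 4 * 1.2, 50 - 10 * 1.2))
  colnames(optima) <- c("t1", "t2")
  widths <- matrix(c(2, 2, 5, 5), 2, 2, dimnames = list(NULL, c("t1", "t2")))
  truth <- ecotype_truth(optima, widths)
  suit <- plant_suitability(stack, truth)
  design <- sample_study(suit, n_districts_per_ecotype = 2,
                         villages_per_district = 2,
                         altitude_bands = list(c(600, 1400), c(1600, 2200)),
                         seed = stable_seed(seed, "study-design"))
  list(stack = stack, design = design)
}

mini_config <- function(sc, seed = 3, out_dir = NULL, ...) {
  run_config(sc$stack, sc$design$table, seed = seed, out_dir = out_dir,
             fc_sets = c("L", "LQ"), bm_list = c(1, 2), k_folds = 5,
             k_range = 2:3, k_override = 2, mvs_bm_list = c(1, 2), ...)
}
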