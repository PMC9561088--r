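test_that("feature construction matches the class definitions", {
  bg <- data.frame(v = runif(50, 10, 30))
  L <- build_features(bg, "L")
  expect_equal(ncol(L$features), 1)
  expect_true(all(L$features >= 0 & L$features <= 1))

  H <- build_features(bg, "H", n_knots = 3)
  expect_equal(ncol(H$features), 6) # forward + reverse per knot
  expect_true(all(H$features >= 0 & H$features <= 1))

  cat_bg <- data.frame(c1 = rep(1:4, 10))
  C <- build_features(cat_bg, "L", kind = c(c1 = "categorical"))
  expect_equal(ncol(C$features), 4) # indicators auto-included
  expect_equal(unname(rowSums(C$features)), rep(1, 40))

  expect_error(feature_space(bg, character(0)), "empty")

  # quadratic and product definitions on scaled values
  bg2 <- data.frame(a = c(0, 5, 10), b = c(10, 20, 30))
  QP <- build_features(bg2, c("L", "Q", "P"))
  fm <- QP$features
  expect_equal(unname(fm[, "Q_a"]), unname(fm[, "L_a"]^2))
  expect_equal(unname(fm[, "P_a_x_b"]),
               unname(fm[, "L_a"] * fm[, "L_b"]))
})

test_that("full shrinkage collapses to the uniform distribution", {
  tp <- toy_problem()
  m <- fit_maxent(tp$features, tp$presence, beta = rep(100, 2))
  expect_equal(m$lambda, c(0, 0))
  raw <- exp(as.numeric(tp$features %*% m$lambda) - m$logZ)
  expect_equal(raw, rep(1 / 20, 20))
  expect_equal(m$entropy, log(20))
})

test_that("coordinate descent matches an independent convex optimizer", {
  tp <- toy_problem()
  for (beta in list(c(0.02, 0.05), c(0.2, 0.2), c(0.001, 0.3))) {
    fit <- fit_maxent(tp$features, tp$presence, beta = beta)
    oracle <- oracle_maxent(tp$features, tp$presence, beta)
    expect_lt(abs(fit$objective - oracle$objective), 1e-6)
  }
})

test_that("the optimum satisfies the KKT conditions of the objective", {
  tp <- toy_problem()
  beta <- c(0.02, 0.05)
  fit <- fit_maxent(tp$features, tp$presence, beta = beta)
  w <- exp(as.numeric(tp$features %*% fit$lambda) - fit$logZ)
  Ej <- as.numeric(t(w) %*% tp$features)
  pbar <- colMeans(tp$features[tp$presence, , drop = FALSE])
  g <- Ej - pbar # gradient of the smooth part
  tol <- 1e-5
  for (j in seq_along(beta)) {
    if (fit$lambda[j] == 0) {
      expect_lte(abs(g[j]), beta[j] + tol)
    } else {
      expect_equal(unname(g[j]), -beta[j] * sign(fit$lambda[j]),
                   tolerance = tol)
    }
  }
})

test_that("the fitted distribution conserves mass and entropy algebra", {
  tp <- toy_problem()
  fit <- fit_maxent(tp$features, tp$presence, beta = c(0.02, 0.05))
  raw <- exp(as.numeric(tp$features %*% fit$lambda) - fit$logZ)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # any cell with raw = e^-H maps to logistic exactly 0.5
  eH <- exp(fit$entropy)
  raw_star <- exp(-fit$entropy)
  expect_equal(raw_star * eH / (1 + raw_star * eH), 0.5)
  # objective is non-increasing across sweeps
  expect_true(all(diff(fit$sweep_objective) <= 1e-12))
})

test_that("projected outputs are rank-consistent and cumulative tops at 100", {
  pm <- planted_mini(seed = 9)
  m <- fit_niche_model(pm$stack, pm$occ, vars = "driver", fc_set = "LQ",
                       bm = 1, n_knots = 8)
  sm <- predict_suitability(m, pm$stack)
  raw <- sm$raw$values[pm$stack$mask]
  lg <- sm$logistic$values[pm$stack$mask]
  cm <- sm$cumulative$values[pm$stack$mask]
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_equal(order(raw), order(lg))
  expect_equal(rank(raw, ties.method = "average"),
               rank(cm, ties.method = "average"))
  expect_equal(cm[which.max(raw)], 100)
  expect_true(all(lg > 0 & lg < 1))
})

test_that("a null model predicts uniform raw and logistic one half", {
  st <- tiny_stack()
  occ <- cell_center(st$layers$a, c(1, 3), c(1, 2))
  names(occ) <- c("lon", "lat")
  m <- fit_niche_model(st, data.frame(lon = occ$lon, lat = occ$lat),
                       fc_set = "L", bm = 1e6)
  expect_true(all(m$lambda == 0))
  sm <- predict_suitability(m, st)
  nb <- sum(st$mask)
  expect_equal(sm$raw$values[st$mask], rep(1 / nb, nb))
  expect_equal(sm$logistic$values[st$mask], rep(0.5, nb))
  expect_equal(model_gain(m)$gain, 0)
})

test_that("total shrinkage grows monotonically with the beta multiplier", {
  tp <- toy_problem()
  specs <- data.frame(feature = c("f1", "f2"), class = "L",
                      var1 = c("f1", "f2"), var2 = NA)
  norms <- vapply(c(0.1, 0.5, 1, 2, 4, 8), function(bm) {
    sum(abs(fit_maxent(tp$features, tp$presence, bm = bm,
                       specs = specs)$lambda))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9))
})

test_that("gain matches direct summation on a hand-built example", {
  # 4 background cells, one linear feature, lambda fixed at 1
  f <- matrix(c(0, 1 / 3, 2 / 3, 1), ncol = 1)
  lambda <- 1
  logZ <- log(sum(exp(f * lambda)))
  pres <- c(3L, 4L)
  gain_direct <- mean(f[pres] * lambda) - logZ + log(4)
  m <- fit_maxent(f, pres, beta = 0.05)
  # overwrite with the fixed coefficient to audit the formula
  m$lambda <- lambda
  m$logZ <- logZ
  m$presence_means <- mean(f[pres])
  g <- model_gain(m)
  expect_equal(g$gain, gain_direct)
  expect_lte(g$regularized_gain, g$gain)
})

test_that("regularization constants interpolate the published table", {
  expect_equal(reg_constant("L", 10), 1.6)
  expect_equal(reg_constant("Q", 100), 0.05) # flat beyond the last break
  expect_equal(reg_constant("H", 7), 0.5)
  expect_equal(reg_constant("T", 50), 1.5)
  expect_equal(reg_constant("C", 13.5), 0.375)
})
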