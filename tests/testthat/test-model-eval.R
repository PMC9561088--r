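test_that("rank AUC equals exhaustive pair counting with half-credit ties", {
  expect_equal(auc_rank(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(auc_rank(c(1, 2, 3), c(1, 2, 3)), 0.5)

  pres <- c(0.9, 0.4); bg <- c(0.4, 0.1)
  brute <- 0
  for (p in pres) for (b in bg) {
    brute <- brute + if (p > b) 1 else if (p == b) 0.5 else 0
  }
  expect_equal(auc_rank(pres, bg), brute / 4)
  expect_equal(auc_rank(pres, bg), 0.875)

  # invariance to monotone transforms
  set.seed(3)
  p2 <- runif(15); b2 <- runif(40)
  expect_equal(auc_rank(p2, b2), auc_rank(exp(3 * p2), exp(3 * b2)))
  expect_error(auc_rank(numeric(0), b2), "empty")
})

test_that("jackknife produces two sub-models per variable plus a reference", {
  pm <- planted_mini(seed = 11)
  jk <- jackknife_importance(pm$stack, pm$occ, c("driver", "noise"),
                             fc_set = "LQ", bm = 1, n_knots = 6)
  expect_equal(nrow(jk$table), 1 + 2 * 2)
  expect_setequal(unique(jk$table$mode),
                  c("reference", "with_only", "without"))

  t <- jk$table
  ref_gain <- t$gain_train[t$mode == "reference"]
  with_driver <- t$gain_train[t$variable == "driver" & t$mode == "with_only"]
  with_noise <- t$gain_train[t$variable == "noise" & t$mode == "with_only"]
  expect_gt(with_driver, with_noise)
  # removing a variable cannot help beyond optimizer tolerance
  expect_true(all(t$gain_train[t$mode == "without"] <= ref_gain + 1e-6))

  expect_error(jackknife_importance(pm$stack, pm$occ, "driver"),
               "at least two")
})

test_that("percent contribution credits the planted driver most", {
  pm <- planted_mini(seed = 13)
  m1 <- fit_niche_model(pm$stack, pm$occ, vars = "driver", fc_set = "LQ")
  expect_equal(unname(percent_contribution(m1)), 100)

  m <- fit_niche_model(pm$stack, pm$occ, vars = c("driver", "noise"),
                       fc_set = "LQ")
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 0.1)
  expect_true(all(pc >= 0))
  expect_equal(names(which.max(pc)), "driver")
})

test_that("permutation importance vanishes for inert variables", {
  pm <- planted_mini(seed = 17)
  m <- fit_niche_model(pm$stack, pm$occ, vars = c("driver", "noise"),
                       fc_set = "LQ")
  pi <- permutation_importance(m, pm$stack, seed = 1)
  expect_equal(sum(pi), 100, tolerance = 0.1)
  expect_equal(names(which.max(pi)), "driver")

  # a variable whose features all carry zero weight cannot matter
  m0 <- m
  sp <- m0$specs
  m0$lambda[sp$var1 == "noise"] <- 0
  pi0 <- permutation_importance(m0, pm$stack, seed = 1)
  expect_equal(unname(pi0["noise"]), 0)
})

test_that("response curves sweep the background range as specified", {
  pm <- planted_mini(seed = 19)
  m <- fit_niche_model(pm$stack, pm$occ, vars = c("driver", "noise"),
                       fc_set = "LQ")
  rc <- response_curve(m, pm$stack, "driver", n_grid = 25)
  expect_equal(nrow(rc), 25)
  bg <- background_table(pm$stack)
  expect_equal(range(rc$value), range(bg$driver))
  expect_error(response_curve(m, pm$stack, "ghost"), "unknown variable")

  # a single positive linear feature gives a non-decreasing curve
  mpos <- fit_niche_model(pm$stack, pm$occ, vars = "driver",
                          fc_set = "L", bm = 0.05)
  if (mpos$lambda[1] > 0) {
    rcp <- response_curve(mpos, pm$stack, "driver", n_grid = 30)
    expect_true(all(diff(rcp$logistic) >= -1e-12))
  }

  # a fully shrunk model responds flat at one half
  mnull <- fit_niche_model(pm$stack, pm$occ, vars = c("driver", "noise"),
                           fc_set = "L", bm = 1e6)
  rc0 <- response_curve(mnull, pm$stack, "driver", n_grid = 10)
  expect_equal(rc0$logistic, rep(0.5, 10))
})
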