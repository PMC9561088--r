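test_that("normality annotation behaves on reference and degenerate input", {
  # exact standard-normal quantiles are as normal as a sample can be
  x <- qnorm(ppoints(50))
  rep <- normality_check(data.frame(norm = x, unif = runif(50, 1, 2),
                                    const = rep(3, 50)))
  expect_gt(rep$W[rep$variable == "norm"], 0.99)
  expect_true(all(rep$W <= 1, na.rm = TRUE))
  expect_true(rep$degenerate[rep$variable == "const"])
  expect_false(any(rep$degenerate[rep$variable != "const"]))
})

test_that("Spearman correlation works on ranks with midrank ties", {
  x <- seq(-2, 2, length.out = 20)
  r <- spearman_matrix(data.frame(x = x, y = exp(x), z = -x))
  expect_equal(r$r["x", "y"], 1)
  expect_equal(r$r["x", "z"], -1)
  expect_true(isSymmetric(r$r))
  expect_equal(unname(diag(r$r)), rep(1, 3))

  # brute-force midrank oracle on a tied vector
  a <- c(1, 1, 2, 3); b <- c(4, 3, 2, 1)
  ra <- rank(a); rb <- rank(b) # midranks
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  got <- spearman_matrix(data.frame(a = a, b = b, pad = c(2, 7, 1, 9)))
  expect_equal(got$r["a", "b"], oracle)
  expect_equal(spearman_strength(c(0.85, 0.7, 0.5, 0.3, 0.1)),
               c("very strong", "strong", "moderate", "weak", "very weak"))
})

test_that("correlation pruning keeps the highest-priority member", {
  mk <- function(m, nm) {
    dimnames(m) <- list(nm, nm)
    list(r = m)
  }
  r2 <- mk(matrix(c(1, .9, .9, 1), 2), c("A", "B"))
  expect_equal(prune_correlated(r2, 0.6, priority = "A"), "A")
  expect_equal(prune_correlated(r2, 0.95), c("A", "B")) # all below

  # chain A~B (.9), B~C (.9), A~C (.1), priority B
  r3 <- mk(matrix(c(1, .9, .1,
                    .9, 1, .9,
                    .1, .9, 1), 3), c("A", "B", "C"))
  kept <- prune_correlated(r3, 0.6, priority = "B")
  expect_equal(kept, "B")
  # exhaustive oracle: among all pairwise-below-threshold subsets that
  # contain the priority variable, B alone and {A, C} are feasible; the
  # greedy priority rule must return the one holding B
  subsets <- unlist(lapply(1:3, function(k) {
    utils::combn(c("A", "B", "C"), k, simplify = FALSE)
  }), recursive = FALSE)
  feasible <- Filter(function(s) {
    all(abs(r3$r[s, s][upper.tri(diag(length(s)))]) < 0.6)
  }, subsets)
  expect_true(list(kept) %in% feasible ||
                any(vapply(feasible, identical, logical(1), kept)))
  expect_true("B" %in% kept)

  # invariance to input column order
  perm <- c("C", "A", "B")
  r3p <- list(r = r3$r[perm, perm])
  expect_setequal(prune_correlated(r3p, 0.6, priority = "B"), kept)
})

test_that("PCA summary conserves variance and flags degeneracy", {
  set.seed(1)
  x <- rnorm(200)
  p <- pca_summary(data.frame(a = x, b = 2 * x + 1))
  expect_equal(p$variance_explained[1], 100)
  expect_equal(sum(p$variance_explained), 100)

  q <- pca_summary(data.frame(a = rnorm(500), b = rnorm(500)))
  expect_equal(q$variance_explained, c(50, 50), tolerance = 0.15)
  expect_equal(sum(q$variance_explained), 100)
  expect_equal(t(q$loadings) %*% q$loadings, diag(2), ignore_attr = TRUE)

  expect_warning(pca_summary(data.frame(a = rnorm(10), b = rnorm(10),
                                        k = rep(1, 10))), "constant")
})

test_that("iterative selection keeps the planted driver and drops noise", {
  pm <- planted_mini(seed = 7)
  sel <- mvs_select(pm$stack, pm$occ, contrib_threshold = 5,
                    corr_threshold = 0.6, bm_list = c(1, 2),
                    fc_set = "LQ", n_knots = 8)
  expect_false("noise" %in% sel$selected)
  # exactly one of the near-duplicate pair survives the correlation rule
  expect_equal(sum(c("driver", "twin") %in% sel$selected), 1)
  # postcondition: the kept set is pairwise below the threshold
  if (length(sel$selected) >= 2) {
    bg <- background_table(pm$stack)[, sel$selected, drop = FALSE]
    rs <- abs(cor(bg, method = "spearman"))
    expect_true(all(rs[upper.tri(rs)] < 0.6))
  }
  # the trace replays to the selected set
  tr <- sel$trace[sel$trace$bm == sel$best_bm, ]
  replay <- setdiff(names(pm$stack$layers), tr$removed)
  expect_setequal(replay, sel$selected)
})
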