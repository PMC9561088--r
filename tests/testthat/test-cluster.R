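test_that("row distances are Euclidean distances between similarity rows", {
  S <- rbind(c(1, 0.5, 0), c(1, 0.5, 1))
  D <- as.matrix(dist(S))
  expect_equal(D[1, 2], 1) # single differing coordinate

  S3 <- matrix(c(1, .8, .2,
                 .8, 1, .3,
                 .2, .3, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  D3 <- row_distance(S3)
  expect_true(isSymmetric(D3))
  expect_equal(unname(diag(D3)), rep(0, 3))
  expect_equal(D3["a", "b"], sqrt(sum((S3["a", ] - S3["b", ])^2)))
  expect_error(row_distance(matrix(1, 2, 3)), "square")
})

test_that("single-linkage merge heights and AC match the hand trace", {
  # 1-D points {0, 1, 10}: merges at heights 1 then 9;
  # AC = mean(1 - 1/9, 1 - 1/9, 1 - 9/9) = 16/27
  D <- as.matrix(dist(c(0, 1, 10)))
  t <- hac(D, "single")
  expect_equal(t$hclust$height, c(1, 9))
  expect_equal(t$ac, 16 / 27)

  dup <- as.matrix(dist(c(3, 3, 7)))
  expect_equal(hac(dup, "single")$hclust$height[1], 0)
})

test_that("AC agrees with the cluster package across linkages", {
  set.seed(8)
  for (i in 1:5) {
    x <- matrix(rnorm(7 * 3), 7)
    D <- as.matrix(dist(x))
    for (l in c("single", "complete", "average", "ward")) {
      mine <- hac(D, l)$ac
      ag <- cluster::agnes(as.dist(D), diss = TRUE,
                           method = if (l == "ward") "ward" else l)$ac
      expect_equal(mine, ag, tolerance = 1e-9)
      expect_gte(mine, 0); expect_lte(mine, 1)
    }
  }
})

test_that("linkage selection maximizes AC with the stated tie order", {
  D <- as.matrix(dist(matrix(rnorm(12), 6)))
  cl <- compare_linkages(D)
  expect_equal(cl$chosen, names(cl$ac)[which.max(cl$ac)])

  fake <- list(ac = c(single = 0.3, ward = 0.8))
  pref <- c("ward", "average", "complete", "single")
  expect_equal(pref[pref %in% names(fake$ac)[fake$ac == max(fake$ac)]][1],
               "ward")
  tied <- c(ward = 0.5, average = 0.5)
  expect_equal(pref[pref %in% names(tied)[tied == max(tied)]][1], "ward")
})

test_that("hac is invariant to label permutation up to relabelling", {
  set.seed(9)
  x <- matrix(rnorm(6 * 2), 6)
  rownames(x) <- paste0("p", 1:6)
  D <- as.matrix(dist(x))
  perm <- sample(6)
  Dp <- D[perm, perm]
  a1 <- cut_assign(hac(D, "ward"), 3)
  a2 <- cut_assign(hac(Dp, "ward"), 3)
  expect_equal(adjusted_rand(a1[rownames(D)], a2[rownames(D)]), 1)
  expect_equal(hac(D, "ward")$ac, hac(Dp, "ward")$ac)
})

planted_blocks <- function(k, per = 4, within = 0.1, between = 5) {
  n <- k * per
  D <- matrix(between, n, n)
  for (b in seq_len(k)) {
    idx <- (b - 1) * per + seq_len(per)
    D[idx, idx] <- within
  }
  diag(D) <- 0
  dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
  D
}

test_that("tree cutting recovers planted blocks and respects k bounds", {
  D <- planted_blocks(2)
  t <- hac(D, "ward")
  a <- cut_assign(t, 2)
  truth <- rep(1:2, each = 4)
  expect_equal(adjusted_rand(a, truth), 1)
  expect_equal(length(unique(cut_assign(t, 8))), 8) # all singletons
  expect_equal(unname(cut_assign(t, 1)), rep(1, 8))
  expect_error(cut_assign(t, 0), "out of range")
  expect_error(cut_assign(t, 9), "out of range")
  # labels numbered by first appearance
  expect_equal(unname(a[1]), 1)
})

test_that("silhouette search finds the planted group count", {
  D4 <- planted_blocks(4)
  t4 <- hac(D4, "ward")
  expect_equal(choose_k(t4, D4, 2:6), 4)
  D2 <- planted_blocks(2)
  t2 <- hac(D2, "ward")
  expect_equal(choose_k(t2, D2, 2:6), 2)
  expect_equal(choose_k(t4, D4, 2:6, override = 4), 4L)
  expect_equal(choose_k(t2, D2, 2:6, override = 4), 4L)
  expect_error(choose_k(t2, D2, integer(0)), "empty")
})

test_that("ecotype maps are member-wise maxima of cumulative outputs", {
  g1 <- make_grid(matrix(runif(16, 0, 100), 4))
  g2 <- make_grid(matrix(runif(16, 0, 100), 4))
  maps <- list(A = g1, B = g2, C = g1)
  asg <- c(A = 1L, B = 2L, C = 1L)
  em <- ecotype_maps(maps, asg)
  expect_equal(length(em), 2)
  expect_equal(em$ecotype_1$values, pmax(g1$values, g1$values))
  expect_equal(em$ecotype_2$values, g2$values) # singleton identity
  two_same <- ecotype_maps(list(A = g1, B = g1), c(A = 1L, B = 1L))
  expect_equal(two_same$ecotype_1$values, g1$values)
  expect_error(ecotype_maps(maps, asg[1:2]), "unassigned")
})

test_that("Newick export round-trips the tree topology", {
  D <- planted_blocks(2, per = 3)
  t <- hac(D, "average")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(t, f)
  phy <- ape::read.tree(f)
  expect_equal(sort(phy$tip.label), sort(rownames(D)))
  expect_equal(ape::Ntip(phy), 6)
})
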