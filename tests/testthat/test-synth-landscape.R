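test_that("generated layers hit their target correlations", {
  nm <- c("a", "b", "c")
  corr <- diag(3); dimnames(corr) <- list(nm, nm)
  corr["a", "b"] <- corr["b", "a"] <- 0.8
  spec <- landscape_spec(nrow = 100, ncol = 100, corr = corr,
                         means = c(a = 0, b = 0, c = 0),
                         sds = c(a = 1, b = 1, c = 1),
                         groups = c(a = "climatic", b = "climatic",
                                    c = "soil"),
                         blur_sigma = 1.5)
  st <- gen_layers(spec, seed = 4)
  bg <- background_table(st)
  r <- cor(bg)
  expect_equal(r["a", "b"], 0.8, tolerance = 0.1)
  expect_lt(abs(r["a", "c"]), 0.1)
  expect_lt(abs(r["b", "c"]), 0.1)

  # identity target: all pairs near zero
  spec0 <- landscape_spec(nrow = 100, ncol = 100,
                          corr = `dimnames<-`(diag(3), list(nm, nm)),
                          means = c(a = 0, b = 0, c = 0),
                          sds = c(a = 1, b = 1, c = 1),
                          groups = c(a = "climatic", b = "climatic",
                                     c = "soil"),
                          blur_sigma = 1.5)
  r0 <- cor(background_table(gen_layers(spec0, seed = 4)))
  expect_true(all(abs(r0[upper.tri(r0)]) < 0.1))

  # determinism
  st2 <- gen_layers(spec, seed = 4)
  expect_identical(st$layers$a$values, st2$layers$a$values)

  bad <- corr; bad["a", "b"] <- bad["b", "a"] <- 1.2
  expect_error(landscape_spec(nrow = 10, ncol = 10, corr = bad,
                              means = c(a = 0, b = 0, c = 0),
                              sds = c(a = 1, b = 1, c = 1),
                              groups = c(a = "climatic", b = "climatic",
                                         c = "soil")),
               "positive semi-definite")
})

test_that("planted suitability follows the Gaussian product formula", {
  sc <- synthetic_scenario(seed = 2)
  s1 <- sc$suitability[[1]]
  expect_equal(max(s1$values, na.rm = TRUE), 1) # normalized to max one

  # spot-check one cell against direct evaluation
  tr <- sc$truth
  r <- 10; c <- 20
  direct <- prod(vapply(tr$drivers, function(d) {
    v <- sc$stack$layers[[d]]$values[r, c]
    exp(-(v - tr$optima[1, d])^2 / (2 * tr$widths[1, d]^2))
  }, numeric(1)))
  raw_max <- max(exp(Reduce(`+`, lapply(tr$drivers, function(d) {
    -(sc$stack$layers[[d]]$values - tr$optima[1, d])^2 /
      (2 * tr$widths[1, d]^2)
  }))), na.rm = TRUE)
  expect_equal(s1$values[r, c], direct / raw_max)

  # symmetry in (v - opt): mirrored displacement, same suitability
  d1 <- tr$drivers[1]
  gauss <- function(v) exp(-(v - tr$optima[1, d1])^2 /
                             (2 * tr$widths[1, d1]^2))
  expect_equal(gauss(tr$optima[1, d1] + 1.3), gauss(tr$optima[1, d1] - 1.3))
})

test_that("the packaged scenario mirrors the sixteen-district design", {
  sc <- synthetic_scenario(seed = 1)
  d <- sc$design
  expect_equal(length(unique(d$table$district)), 16)
  expect_equal(nrow(d$table), 32)
  expect_equal(sum(vapply(d$occurrences, nrow, integer(1))), 320)
  expect_equal(nrow(d$truth), 16)
  expect_equal(as.vector(table(d$truth$ecotype)), rep(4L, 4))

  # sampling bias: villages sit on better-than-average true suitability
  for (k in 1:4) {
    g <- sc$suitability[[k]]
    dd <- d$truth$district[d$truth$ecotype == k]
    vil <- d$table[d$table$district %in% dd, ]
    cc <- xy_to_cell(g, vil$longitude, vil$latitude)
    at_vil <- mean(g$values[cbind(cc$row, cc$col)])
    expect_gt(at_vil, mean(g$values, na.rm = TRUE))
  }

  # determinism of the full scenario
  sc2 <- synthetic_scenario(seed = 1)
  expect_identical(sc$design$table, sc2$design$table)
  expect_identical(sc$stack$layers$bio5$values, sc2$stack$layers$bio5$values)
})
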