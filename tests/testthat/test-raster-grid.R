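test_that("ASCII grid write-then-read is the identity on values and transform", {
  m <- matrix(c(1.5, -2.25, 30000.125, NA, 0.001, 7), 2, 3)
  g <- make_grid(m, xll = 36.5, yll = 12.25, cellsize = 0.05)
  f <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, f)
  g2 <- read_grid(f, format = "ascii_grid")
  expect_equal(g2$values, g$values)
  expect_equal(g2$xll, g$xll)
  expect_equal(g2$yll, g$yll)
  expect_equal(g2$cellsize, g$cellsize)
})

test_that("nodata cells are excluded from validity", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2", "-9999 4"), f)
  g <- read_grid(f)
  expect_equal(sum(!is.na(g$values)), 3)
  expect_true(is.na(g$values[2, 1]))
})

test_that("grids without georeferencing are rejected by name", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "cellsize 1", "1 2"), f)
  expect_error(read_grid(f), "georeferencing")

  # TIFF with no world file
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(12), 3, 4), tf, bits.per.sample = 32L)
  expect_error(read_grid(tf, format = "geotiff"), "world file")
})

test_that("TIFF plus world file reads values and placement", {
  m <- matrix(runif(12), 3, 4) # float TIFF storage is exact on [0,1]
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, tf, bits.per.sample = 32L)
  wf <- sub("\\.tif$", ".tfw", tf)
  # A D B E C F: 0.01 cells, upper-left centre at (38.005, 13.995)
  writeLines(c("0.01", "0", "0", "-0.01", "38.005", "13.995"), wf)
  g <- read_grid(tf)
  expect_equal(g$values, m, tolerance = 1e-6)
  expect_equal(g$xll, 38.0)
  expect_equal(g$yll, 14 - 3 * 0.01)
  expect_equal(g$cellsize, 0.01)
})

test_that("points map to half-open cells anchored at the upper-left", {
  g <- make_grid(matrix(1:16, 4, 4), xll = 0, yll = 0, cellsize = 1)
  # west/north edges belong to the cell; east/south edges to the next
  expect_equal(unlist(xy_to_cell(g, 0, 4)), c(row = 1L, col = 1L))
  expect_equal(unlist(xy_to_cell(g, 1, 4)), c(row = 1L, col = 2L))
  expect_equal(unlist(xy_to_cell(g, 0.5, 3.5)), c(row = 1L, col = 1L))
  expect_equal(unlist(xy_to_cell(g, 3.999, 0.001)), c(row = 4L, col = 4L))
  expect_true(all(is.na(xy_to_cell(g, -0.01, 2))))
  # centre round-trips
  cc <- cell_center(g, 2, 3)
  expect_equal(unlist(xy_to_cell(g, cc$x, cc$y)), c(row = 2L, col = 3L))
})

test_that("alignment duplicates coarse cells under nearest-neighbour", {
  coarse <- make_grid(matrix(c(1, 3, 2, 4), 2, 2), xll = 0, yll = 0,
                      cellsize = 2)
  template <- make_grid(matrix(0, 4, 4), xll = 0, yll = 0, cellsize = 1)
  st <- align_stack(list(x = coarse), template, method = "nearest")
  got <- st$layers$x$values
  # brute-force oracle: each template cell centre looked up in the source
  expected <- matrix(NA_real_, 4, 4)
  for (r in 1:4) for (c in 1:4) {
    ctr <- cell_center(template, r, c)
    cc <- xy_to_cell(coarse, ctr$x, ctr$y)
    expected[r, c] <- coarse$values[cc$row, cc$col]
  }
  expect_equal(got, expected)
  # each source cell appears in its 2x2 block of children
  expect_equal(got[1:2, 1:2], matrix(1, 2, 2))
  expect_equal(got[3:4, 3:4], matrix(4, 2, 2))
})

test_that("alignment is idempotent and rejects disjoint extents", {
  st <- tiny_stack()
  tmpl <- st$layers$a
  aligned <- align_stack(st$layers, tmpl, method = "bilinear",
                         kind = st$kind, groups = st$groups)
  expect_equal(aligned$layers$a$values, st$layers$a$values)
  expect_equal(aligned$layers$b$values, st$layers$b$values)

  far <- make_grid(matrix(1, 2, 2), xll = 120, yll = -40, cellsize = 1)
  expect_error(align_stack(list(far = far), tmpl), "overlap")
})

test_that("the stack mask shrinks monotonically as layers are added", {
  a <- make_grid(matrix(1, 3, 3))
  b <- make_grid(matrix(c(1, NA, 1, 1, 1, 1, NA, 1, 1), 3, 3))
  s1 <- env_stack(list(a = a))
  s2 <- env_stack(list(a = a, b = b))
  expect_true(all(which(s2$mask) %in% which(s1$mask)))
  expect_equal(sum(s2$mask), 7)
})

test_that("extraction returns per-point status instead of dropping points", {
  st <- tiny_stack()
  ctr <- cell_center(st$layers$a, c(1, 2), c(1, 3))
  pts <- data.frame(lon = c(ctr$x, 39.5), lat = c(ctr$y, 13.5))
  ext <- extract_at(st, pts)
  expect_equal(ext$status, c("ok", "masked", "outside"))
  expect_equal(ext$a[1], 11)
  expect_true(is.na(ext$a[2])) # masked through layer b
  # masked and outside rows keep their coordinates
  expect_equal(ext$lon[3], 39.5)
})

test_that("extraction after alignment agrees with direct cell lookup", {
  st <- tiny_stack()
  tmpl <- st$layers$a
  aligned <- align_stack(st$layers, tmpl, kind = st$kind,
                         groups = st$groups)
  for (r in 1:4) for (c in 1:4) {
    if (!st$mask[r, c]) next
    ctr <- cell_center(tmpl, r, c)
    ext <- extract_at(aligned, data.frame(lon = ctr$x, lat = ctr$y))
    expect_equal(ext$a, st$layers$a$values[r, c])
    expect_equal(ext$b, st$layers$b$values[r, c])
  }
})

test_that("stack round-trips through a manifest directory", {
  st <- tiny_stack()
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  st2 <- read_stack(file.path(dir, "manifest.csv"))
  expect_equal(st2$layers$a$values, st$layers$a$values)
  expect_equal(st2$groups, st$groups)
  expect_equal(st2$mask, st$mask)
  # a manifest naming a missing layer aborts with the layer name
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  man$path[2] <- "gone.asc"
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_stack(file.path(dir, "manifest.csv")), "b")
})
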