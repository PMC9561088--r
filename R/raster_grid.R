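# Gridded environmental layers on a regular geographic grid.
#
# A raster_grid is a rectangular matrix of cell values plus an affine anchor:
# square cells of size `cellsize` (degrees), lower-left corner at
# (xll, yll), row 1 = northernmost row (the ESRI ASCII grid reading order).
# Cell semantics: a value applies to its whole cell; cells are half-open with
# the origin at the upper-left, so a point maps to a cell by flooring the
# inverse transform.

#' Construct a raster grid
#'
#' @param values numeric matrix of cell values; row 1 is the northernmost row.
#'   Invalid cells are `NA`.
#' @param xll,yll x/y coordinate (degrees) of the lower-left corner of the grid.
#' @param cellsize cell edge length in degrees (square cells).
#' @param nodata sentinel written for `NA` cells on output (default -9999).
#' @param crs coordinate reference identifier; the workflow operates in
#'   geographic WGS84 throughout.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                        crs = "EPSG:4326") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values),
            length(xll) == 1L, length(yll) == 1L,
            is.finite(cellsize), cellsize > 0)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = nodata, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf("<raster_grid> %d x %d cells, cellsize %g (%s)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]; %d valid cells\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"],
              sum(!is.na(x$values))))
  invisible(x)
}

#' Grid extent
#'
#' @param grid a `raster_grid`.
#' @return Named numeric vector `xmin, xmax, ymin, ymax` (outer cell edges).
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$xll,
    xmax = grid$xll + ncol(grid$values) * grid$cellsize,
    ymin = grid$yll,
    ymax = grid$yll + nrow(grid$values) * grid$cellsize)
}

#' Map points to cell indices
#'
#' Cells are half-open with the origin at the upper-left: a point on a cell's
#' west or north edge belongs to that cell.
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates (degrees).
#' @return data.frame with columns `row`, `col` (NA where outside the extent).
#' @export
xy_to_cell <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  ytop <- grid$yll + nrow(grid$values) * grid$cellsize
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row <- floor((ytop - y) / grid$cellsize) + 1
  bad <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @param grid a `raster_grid`.
#' @param row,col cell indices (row 1 = northernmost).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_center <- function(grid, row, col) {
  ytop <- grid$yll + nrow(grid$values) * grid$cellsize
  data.frame(x = grid$xll + (col - 0.5) * grid$cellsize,
             y = ytop - (row - 0.5) * grid$cellsize)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Read a single-band raster layer
#'
#' Supports the ESRI ASCII grid dialect (read and write) and single-band TIFF
#' rasters georeferenced by an ESRI world file (`.tfw`/`.wld` sidecar with
#' north-up square pixels; embedded GeoTIFF tags are not parsed). A TIFF
#' without a world file is rejected as missing georeferencing.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ascii_grid"` or `"geotiff"`.
#' @return A [raster_grid()].
#' @export
read_grid <- function(path, format = c("auto", "ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("raster layer not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "geotiff" else "ascii_grid"
  }
  switch(format,
         ascii_grid = read_ascii_grid(path),
         geotiff = read_tiff_grid(path))
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop("malformed ASCII grid header in ", path, ": '", lines[i], "'",
           call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid ", path, " is missing header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter)) {
    stop("ASCII grid ", path,
         " has no georeferencing (xllcorner/xllcenter missing)",
         call. = FALSE)
  }
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid ", path, ": expected ", nr * nc, " cell values, found ",
         length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, xll = xll, yll = yll, cellsize = hdr$cellsize,
              nodata = nodata)
}

world_file_for <- function(path) {
  base <- tools::file_path_sans_ext(path)
  cands <- paste0(base, c(".tfw", ".wld"))
  cands[file.exists(cands)][1]
}

read_tiff_grid <- function(path) {
  wf <- world_file_for(path)
  if (is.na(wf) || is.null(wf)) {
    stop("TIFF layer ", path, " has no georeferencing: expected a world file ",
         "(", tools::file_path_sans_ext(basename(path)), ".tfw)",
         call. = FALSE)
  }
  w <- as.numeric(readLines(wf, warn = FALSE))
  if (length(w) < 6 || anyNA(w[1:6])) {
    stop("malformed world file ", wf, call. = FALSE)
  }
  # A, D, B, E, C, F: x size, rotations, y size (negative), UL centre x/y
  if (w[2] != 0 || w[3] != 0) {
    stop("rotated grids are not supported (world file ", wf, ")",
         call. = FALSE)
  }
  if (abs(w[1] + w[4]) > 1e-9 * abs(w[1])) {
    stop("non-square pixels in world file ", wf, call. = FALSE)
  }
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) {
    stop("multi-band TIFF not supported: ", path, call. = FALSE)
  }
  m[is.nan(m)] <- NA_real_
  cs <- w[1]
  xll <- w[5] - cs / 2
  ytop <- w[6] + cs / 2
  raster_grid(m, xll = xll, yll = ytop - nrow(m) * cs, cellsize = cs)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' `NA` cells are written as the grid's nodata sentinel. `write_grid()`
#' followed by [read_grid()] is the identity on values and georeferencing.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", ncol(grid$values)),
           sprintf("nrows %d", nrow(grid$values)),
           sprintf("xllcorner %.12g", grid$xll),
           sprintf("yllcorner %.12g", grid$yll),
           sprintf("cellsize %.12g", grid$cellsize),
           sprintf("NODATA_value %.12g", grid$nodata))
  body <- apply(m, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
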