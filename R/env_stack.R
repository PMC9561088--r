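# A named, grouped stack of grid-aligned environmental layers — the covariate
# space of the niche models. All layers share one geometry; the stack mask is
# the conjunction of per-layer validity.

#' Assemble an environmental stack from aligned layers
#'
#' @param layers named list of [raster_grid()] objects sharing one geometry.
#' @param groups named character vector mapping layer name to one of
#'   `"climatic"`, `"soil"`, `"vegetation_landcover"`.
#' @param kind named character vector mapping layer name to `"continuous"` or
#'   `"categorical"`. Defaults to continuous for all layers.
#' @return An object of class `env_stack` with fields `layers`, `groups`,
#'   `kind` and `mask` (logical matrix, TRUE where every layer is valid).
#' @export
env_stack <- function(layers, groups = NULL, kind = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), !anyDuplicated(names(layers)))
  nm <- names(layers)
  tmpl <- layers[[1]]
  for (l in nm) {
    if (!inherits(layers[[l]], "raster_grid")) {
      stop("layer '", l, "' is not a raster_grid", call. = FALSE)
    }
    if (!same_geometry(layers[[l]], tmpl)) {
      stop("layer '", l, "' is not on the shared grid; align_stack() first",
           call. = FALSE)
    }
  }
  if (is.null(groups)) groups <- setNames(rep("climatic", length(nm)), nm)
  if (is.null(kind)) kind <- setNames(rep("continuous", length(nm)), nm)
  stopifnot(all(nm %in% names(groups)), all(nm %in% names(kind)))
  groups <- groups[nm]; kind <- kind[nm]
  stopifnot(all(groups %in% c("climatic", "soil", "vegetation_landcover")),
            all(kind %in% c("continuous", "categorical")))
  mask <- Reduce(`&`, lapply(layers, function(g) !is.na(g$values)))
  structure(list(layers = layers, groups = groups, kind = kind, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s), %d x %d cells, %d valid\n",
              length(x$layers),
              paste(sprintf("%s: %d", names(table(x$groups)), table(x$groups)),
                    collapse = ", "),
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

stack_template <- function(stack) stack$layers[[1]]

#' Background covariate table of an environmental stack
#'
#' One row per valid (masked-in) cell, one column per layer, in row-major cell
#' order. These rows are the presence-background model's background sample.
#'
#' @param stack an [env_stack()].
#' @return data.frame of covariates with attribute `cell_index` (the linear
#'   index of each row's cell in the grid matrix).
#' @export
background_table <- function(stack) {
  idx <- which(stack$mask)
  out <- as.data.frame(lapply(stack$layers, function(g) g$values[idx]))
  names(out) <- names(stack$layers)
  attr(out, "cell_index") <- idx
  out
}

#' Resample layers onto a template grid
#'
#' Continuous layers use the requested method (bilinear by default);
#' categorical layers always use nearest-neighbour. Bilinear interpolation is
#' between the four surrounding source cell centres and propagates nodata.
#' Layers already on the template geometry pass through unchanged, so
#' alignment is idempotent.
#'
#' @param grids named list of [raster_grid()] objects.
#' @param template a [raster_grid()] defining the target geometry.
#' @param method `"bilinear"` or `"nearest"` for continuous layers.
#' @param groups,kind passed through to [env_stack()].
#' @return An [env_stack()] on the template geometry.
#' @export
align_stack <- function(grids, template, method = c("bilinear", "nearest"),
                        groups = NULL, kind = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(template, "raster_grid"))
  if (is.null(kind)) {
    kind <- setNames(rep("continuous", length(grids)), names(grids))
  }
  out <- lapply(names(grids), function(nm) {
    g <- grids[[nm]]
    if (!identical(g$crs, template$crs)) {
      stop("layer '", nm, "' CRS (", g$crs, ") differs from template (",
           template$crs, "); reprojection is out of scope", call. = FALSE)
    }
    if (same_geometry(g, template)) return(g)
    e_g <- grid_extent(g); e_t <- grid_extent(template)
    if (e_g["xmin"] >= e_t["xmax"] || e_g["xmax"] <= e_t["xmin"] ||
        e_g["ymin"] >= e_t["ymax"] || e_g["ymax"] <= e_t["ymin"]) {
      stop("layer '", nm, "' does not overlap the template extent",
           call. = FALSE)
    }
    m <- if (identical(kind[[nm]], "categorical")) "nearest" else method
    resample_grid(g, template, m)
  })
  names(out) <- names(grids)
  env_stack(out, groups = groups, kind = kind)
}

resample_grid <- function(src, template, method) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  ctr <- cell_center(template, rows, cols)
  v <- if (method == "nearest") {
    cc <- xy_to_cell(src, ctr$x, ctr$y)
    ifelse(is.na(cc$row), NA_real_,
           src$values[cbind(cc$row, cc$col)])
  } else {
    bilinear_at(src, ctr$x, ctr$y)
  }
  out <- matrix(NA_real_, nr, nc)
  out[cbind(rows, cols)] <- v
  raster_grid(out, template$xll, template$yll, template$cellsize,
              nodata = src$nodata, crs = template$crs)
}

# Bilinear interpolation between the 4 surrounding source cell centres;
# clamped to the centre lattice at the edges; NA if any contributor is NA.
bilinear_at <- function(src, x, y) {
  nr <- nrow(src$values); nc <- ncol(src$values)
  ytop <- src$yll + nr * src$cellsize
  # fractional position on the cell-centre lattice
  fc <- (x - src$xll) / src$cellsize + 0.5
  fr <- (ytop - y) / src$cellsize + 0.5
  out <- rep(NA_real_, length(x))
  inside <- fc >= 0.5 & fc <= nc + 0.5 & fr >= 0.5 & fr <= nr + 0.5
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1); c0 <- pmax(c0, 1)
  r0 <- pmin(floor(fr), nr - 1); r0 <- pmax(r0, 1)
  wx <- fc - c0; wy <- fr - r0
  v00 <- src$values[cbind(r0, c0)]
  v01 <- src$values[cbind(r0, c0 + 1)]
  v10 <- src$values[cbind(r0 + 1, c0)]
  v11 <- src$values[cbind(r0 + 1, c0 + 1)]
  val <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
    wy * ((1 - wx) * v10 + wx * v11)
  out[inside] <- val[inside]
  out
}

#' Extract stack covariates at points
#'
#' @param stack an [env_stack()].
#' @param points data.frame with columns `lon`, `lat` (degrees).
#' @return data.frame with one row per point: the point coordinates, a
#'   `status` column (`"ok"`, `"masked"` for points in nodata cells,
#'   `"outside"` for points beyond the extent) and one column per layer
#'   (NA unless status is `"ok"`). Out-of-extent points yield an error record,
#'   never a silent drop.
#' @export
extract_at <- function(stack, points) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  tmpl <- stack_template(stack)
  cc <- xy_to_cell(tmpl, points$lon, points$lat)
  n <- nrow(points)
  status <- rep("ok", n)
  status[is.na(cc$row)] <- "outside"
  ok <- !is.na(cc$row)
  masked <- rep(FALSE, n)
  masked[ok] <- !stack$mask[cbind(cc$row[ok], cc$col[ok])]
  status[masked] <- "masked"
  vals <- lapply(stack$layers, function(g) {
    v <- rep(NA_real_, n)
    take <- status == "ok"
    v[take] <- g$values[cbind(cc$row[take], cc$col[take])]
    v
  })
  out <- data.frame(lon = points$lon, lat = points$lat, status = status)
  out <- cbind(out, as.data.frame(vals))
  out
}

#' Write an environmental stack as ASCII grids plus a manifest
#'
#' Each layer is written as `<name>.asc` and a `manifest.csv`
#' (`name, group, kind, path`) is placed alongside, so the directory can be
#' re-read with [read_stack()].
#'
#' @param stack an [env_stack()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- names(stack$layers)
  paths <- paste0(nm, ".asc")
  for (i in seq_along(nm)) {
    write_grid(stack$layers[[i]], file.path(dir, paths[i]))
  }
  man <- data.frame(name = nm, group = unname(stack$groups[nm]),
                    kind = unname(stack$kind[nm]), path = paths,
                    stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Read an environmental stack from a layer manifest
#'
#' The manifest is a CSV with columns `name, group, kind, path`; relative
#' paths resolve against the manifest's directory. Layers are read with
#' [read_grid()] and aligned to the first layer's geometry.
#'
#' @param manifest_path path to the manifest CSV.
#' @param method resampling method for continuous layers needing alignment.
#' @return An [env_stack()].
#' @export
read_stack <- function(manifest_path, method = "bilinear") {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("name", "group", "kind", "path")
  if (!all(need %in% names(man))) {
    stop("layer manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(dir, man$path))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("layer manifest references missing layer(s): ",
         paste(man$name[missing], collapse = ", "), call. = FALSE)
  }
  grids <- lapply(paths, read_grid)
  names(grids) <- man$name
  align_stack(grids, grids[[1]], method = method,
              groups = setNames(man$group, man$name),
              kind = setNames(man$kind, man$name))
}
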