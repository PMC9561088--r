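# Pairwise comparison of suitability maps: Pearson correlation of the
# logistic surfaces, and distribution overlap (Hellinger-based I, Schoener's
# D) of the renormalized raw surfaces.

joint_cells <- function(a, b, min_cells = 10) {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  if (!same_geometry(a, b)) {
    stop("maps are not on the same grid", call. = FALSE)
  }
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < min_cells) {
    stop("fewer than ", min_cells, " jointly valid cells", call. = FALSE)
  }
  ok
}

map_of <- function(x, output) {
  if (inherits(x, "suitability_map")) x[[output]] else x
}

#' Pearson correlation between two suitability maps
#'
#' Computed on the logistic outputs over jointly valid cells.
#'
#' @param a,b `suitability_map` objects (or raster_grids).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_maps <- function(a, b) {
  ga <- map_of(a, "logistic"); gb <- map_of(b, "logistic")
  ok <- joint_cells(ga, gb)
  x <- ga$values[ok]; y <- gb$values[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant suitability map: correlation undefined", call. = FALSE)
  }
  cor(x, y)
}

# renormalize two maps to probability distributions on the joint mask
joint_distributions <- function(a, b) {
  ga <- map_of(a, "raw"); gb <- map_of(b, "raw")
  ok <- joint_cells(ga, gb)
  p <- ga$values[ok]; q <- gb$values[ok]
  if (any(p < 0) || any(q < 0)) stop("negative suitability", call. = FALSE)
  if (sum(p) <= 0 || sum(q) <= 0) {
    stop("all-zero suitability map", call. = FALSE)
  }
  list(p = p / sum(p), q = q / sum(q))
}

#' Niche overlap I (Hellinger-based)
#'
#' `I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)` over the two maps renormalized
#' to sum to one on jointly valid cells: 1 for identical niches, 0 for
#' disjoint ones. Invariant to positive rescaling of either map.
#'
#' @param a,b `suitability_map` objects (or raster_grids of non-negative
#'   suitability).
#' @return Overlap in \[0, 1\].
#' @export
niche_overlap_I <- function(a, b) {
  d <- joint_distributions(a, b)
  1 - 0.5 * sum((sqrt(d$p) - sqrt(d$q))^2)
}

#' Schoener's D overlap
#'
#' `D = 1 - 0.5 * sum(|p - q|)`: one minus the total-variation distance
#' between the renormalized suitability distributions.
#'
#' @inheritParams niche_overlap_I
#' @return Overlap in \[0, 1\].
#' @export
schoener_D <- function(a, b) {
  d <- joint_distributions(a, b)
  1 - 0.5 * sum(abs(d$p - d$q))
}

#' Population-by-population similarity matrix
#'
#' @param maps named list of `suitability_map` objects on a common grid.
#' @param metric `"pearson_r"`, `"overlap_I"` or `"schoener_D"`.
#' @return A `similarity_matrix`: square symmetric matrix with unit
#'   diagonal, labelled by population, with attribute `metric`.
#' @export
similarity_matrix <- function(maps,
                              metric = c("pearson_r", "overlap_I",
                                         "schoener_D")) {
  metric <- match.arg(metric)
  stopifnot(length(maps) >= 2, !is.null(names(maps)))
  fun <- switch(metric, pearson_r = pearson_maps,
                overlap_I = niche_overlap_I, schoener_D = schoener_D)
  n <- length(maps)
  S <- matrix(1, n, n, dimnames = list(names(maps), names(maps)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- fun(maps[[i]], maps[[j]])
    }
  }
  attr(S, "metric") <- metric
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Long-format view of a similarity matrix
#'
#' @param S a [similarity_matrix()].
#' @return data.frame `pop_a, pop_b, value` (upper triangle).
#' @export
similarity_long <- function(S) {
  nm <- colnames(S)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  data.frame(pop_a = nm[idx[, 1]], pop_b = nm[idx[, 2]],
             value = S[idx], stringsAsFactors = FALSE)
}
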