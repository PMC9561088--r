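# From similarity matrices to ecotype assignments: Euclidean distances
# between similarity-matrix rows, agglomerative clustering under four
# linkages, linkage selection by agglomerative coefficient, tree cutting,
# and per-ecotype combined suitability maps.

#' Euclidean distances between similarity-matrix rows
#'
#' Each population is represented by its row of pairwise similarities; the
#' distance between two populations is the Euclidean distance between their
#' rows (the protocol clusters these row distances, not 1 - similarity).
#'
#' @param S square symmetric similarity matrix with labels.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
row_distance <- function(S) {
  S <- unclass(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square",
                               call. = FALSE)
  as.matrix(dist(S, method = "euclidean"))
}

#' Agglomerative clustering with agglomerative coefficient
#'
#' Standard agglomerative merging under the named linkage (Ward via the
#' Lance-Williams update on squared distances with heights reported on the
#' distance scale, i.e. the ward.D2 convention). The agglomerative
#' coefficient is the mean over objects of one minus the ratio of the
#' object's first-merge height to the final merge height.
#'
#' @param D distance matrix (symmetric, non-negative, zero diagonal) or
#'   `dist`.
#' @param linkage `"single"`, `"complete"`, `"average"` or `"ward"`.
#' @return A `cluster_tree`: the `hclust` object, `linkage`, and `ac`.
#' @export
hac <- function(D, linkage = c("ward", "average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(D, "dist")) D else as.dist(D)
  if (attr(d, "Size") < 2) stop("need at least 2 objects", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(d, method = method)
  structure(list(hclust = hc, linkage = linkage,
                 ac = agglomerative_coefficient(hc)),
            class = "cluster_tree")
}

#' Agglomerative coefficient from a merge trace
#'
#' `AC = mean_i (1 - m(i) / m_final)` where `m(i)` is the height at which
#' object i first merges and `m_final` the height of the last merge.
#'
#' @param hc an `hclust` object.
#' @return AC in \[0, 1\].
#' @export
agglomerative_coefficient <- function(hc) {
  n <- length(hc$order)
  first <- numeric(n)
  for (k in seq_along(hc$height)) {
    for (obj in hc$merge[k, ]) {
      if (obj < 0) first[-obj] <- hc$height[k]
    }
  }
  m_final <- hc$height[length(hc$height)]
  if (m_final <= 0) return(0)
  mean(1 - first / m_final)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d objects, %s linkage, AC = %.4f\n",
              length(x$hclust$order), x$linkage, x$ac))
  invisible(x)
}

#' Cluster under all four linkages and select by agglomerative coefficient
#'
#' @param D distance matrix.
#' @param linkages linkage methods to compare.
#' @return list `trees` (per linkage), `ac` (named vector), `chosen` (the
#'   linkage with the largest AC; ties resolved ward > average > complete >
#'   single).
#' @export
compare_linkages <- function(D, linkages = c("single", "complete",
                                             "average", "ward")) {
  trees <- lapply(setNames(linkages, linkages), function(l) hac(D, l))
  ac <- vapply(trees, function(t) t$ac, numeric(1))
  pref <- c("ward", "average", "complete", "single")
  cand <- names(ac)[ac == max(ac)]
  chosen <- pref[pref %in% cand][1]
  list(trees = trees, ac = ac, chosen = chosen)
}

#' Cut a cluster tree into k ecotypes
#'
#' @param tree a `cluster_tree`.
#' @param k number of groups, between 1 and n.
#' @return Named integer vector population -> ecotype, labels numbered by
#'   first appearance order of the populations.
#' @export
cut_assign <- function(tree, k) {
  n <- length(tree$hclust$order)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]", call. = FALSE)
  raw <- cutree(tree$hclust, k = k)
  # renumber by first appearance
  lev <- unique(raw)
  out <- setNames(match(raw, lev), names(raw))
  out
}

#' Choose k by mean silhouette width
#'
#' Maximizes the mean silhouette width over `k_range` on the supplied
#' distance matrix; an explicit `override` short-circuits the search (the
#' protocol's final group count is a judgement call that the configuration
#' can pin).
#'
#' @param tree a `cluster_tree`.
#' @param D the distance matrix the tree was built from.
#' @param k_range candidate group counts (subset of 2..n-1).
#' @param override fixed k, or `NULL` to search.
#' @return Selected k.
#' @export
choose_k <- function(tree, D, k_range = 2:6, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  n <- length(tree$hclust$order)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("empty k range", call. = FALSE)
  d <- as.dist(D)
  sil <- vapply(k_range, function(k) {
    cl <- cutree(tree$hclust, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k_range[which.max(sil)]
}

#' Combine member suitability maps per ecotype
#'
#' A cell is suitable for an ecotype if it is suitable for any member
#' population: the combined map is the cell-wise maximum of the members'
#' cumulative maps.
#'
#' @param maps named list of `suitability_map` objects.
#' @param assignment named vector population -> ecotype from
#'   [cut_assign()].
#' @return Named list (one raster_grid per ecotype label).
#' @export
ecotype_maps <- function(maps, assignment) {
  miss <- setdiff(names(maps), names(assignment))
  if (length(miss) > 0) {
    stop("unassigned population(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labs <- sort(unique(assignment[names(maps)]))
  out <- lapply(setNames(labs, paste0("ecotype_", labs)), function(lb) {
    members <- names(maps)[assignment[names(maps)] == lb]
    grids <- lapply(maps[members], map_of, output = "cumulative")
    vals <- Reduce(function(a, b) pmax(a, b, na.rm = FALSE),
                   lapply(grids, function(g) g$values))
    g1 <- grids[[1]]
    raster_grid(vals, g1$xll, g1$yll, g1$cellsize, crs = g1$crs)
  })
  out
}

#' Export a cluster tree in Newick format
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param tree a `cluster_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
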