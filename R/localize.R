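# Plant localization: density clustering of a bare-stem height layer.
# Each cluster of stem points yields one localization point
# A_pk = (mean x, mean y, L_h), the plant's persistent identity in the
# field registry.

#' Extract a height layer from a plant cloud
#'
#' Keeps exactly the points with `l_low <= z <= l_high` (closed interval).
#' Original point indices are preserved in the `source_indices` attribute.
#'
#' @param gp aligned plant [point_cloud] (ground at z = 0).
#' @param layer numeric (l_low, l_high) in meters, `0 <= l_low < l_high`.
#' @return a [point_cloud] (possibly empty: no plants in the layer).
#' @export
slice_layer <- function(gp, layer) {
  if (!(layer[1] >= 0 && layer[1] < layer[2]))
    stop("layer must satisfy 0 <= l_low < l_high")
  z <- gp$points[, 3]
  subset_cloud(gp, z >= layer[1] & z <= layer[2])
}

#' Density-derived DBSCAN neighborhood radius
#'
#' For m points spanning an axis-aligned box of volume
#' `T = prod(max X_i - min X_i)` in n dimensions, the radius whose
#' n-ball is expected to hold MinPts points under uniform density:
#' `eps = (T * MinPts * Gamma(n/2 + 1) / (m * pi^(n/2)))^(1/n)`.
#'
#' @param points a [point_cloud] or coordinate matrix.
#' @param min_pts DBSCAN MinPts.
#' @param dims 3 (default) or 2 (layer projected to the ground plane).
#' @return eps in meters.
#' @export
auto_epsilon <- function(points, min_pts, dims = 3L) {
  pts <- if (inherits(points, "point_cloud")) points$points else
    as.matrix(points)
  pts <- pts[, seq_len(dims), drop = FALSE]
  m <- nrow(pts)
  if (m < min_pts) stop("need at least MinPts points")
  ranges <- apply(pts, 2, function(v) diff(range(v)))
  if (any(ranges <= 0)) stop("zero-extent bounding box")
  Tvol <- prod(ranges)
  n <- dims
  (Tvol * min_pts * gamma(n / 2 + 1) / (m * pi^(n / 2)))^(1 / n)
}

#' DBSCAN clustering of a point cloud
#'
#' Exact density-reachability clustering. Core points (at least `min_pts`
#' points within `eps`, the point itself included) form clusters as
#' connected components of the core-core eps graph, numbered in order of
#' their smallest point index; border points join the lowest-id cluster
#' among their core neighbors; everything else is noise.
#'
#' @param points a [point_cloud] or coordinate matrix.
#' @param eps neighborhood radius (m), > 0.
#' @param min_pts minimum neighborhood size for a core point, >= 1.
#' @return list with `clusters` (list of integer index vectors, cluster k
#'   at position k) and `noise` (integer indices).
#' @export
dbscan_clusters <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  pts <- if (inherits(points, "point_cloud")) points$points else
    as_xyz_matrix(points, "points")
  labels <- cpp_dbscan(pts, eps, as.integer(min_pts))
  ks <- sort(unique(labels[labels > 0L]))
  list(
    clusters = lapply(ks, function(k) which(labels == k)),
    noise = which(labels == 0L),
    labels = labels
  )
}

#' Per-plant localization points from root clusters
#'
#' A_pk = (mean x over C_k, mean y over C_k, L_h): the cluster's horizontal
#' centroid pinned at the top of the localization layer. Plant indices are
#' assigned in row-major field order (by y, then x).
#'
#' @param clusters list of integer index vectors (from [dbscan_clusters]).
#' @param source the [point_cloud] the indices refer to.
#' @param layer numeric (l_low, l_high); locators sit at z = l_high.
#' @return data.frame with columns `plant_index`, `x`, `y`, `z`.
#' @export
localization_points <- function(clusters, source, layer) {
  if (!length(clusters)) stop("no clusters")
  pts <- source$points
  xy <- t(vapply(clusters, function(idx)
    c(mean(pts[idx, 1]), mean(pts[idx, 2])), numeric(2)))
  ord <- order(xy[, 2], xy[, 1])
  data.frame(plant_index = seq_along(clusters),
             x = xy[ord, 1], y = xy[ord, 2], z = layer[2])
}

#' Build the field registry
#'
#' One row per plant: variety, plot, plant index and the localization
#' point. The registry is the stable identity joining segmentation output
#' to trait records.
#'
#' @param locators data.frame from [localization_points].
#' @param variety variety code.
#' @param plot plot code.
#' @return data.frame with columns `variety`, `plot`, `plant_index`,
#'   `x`, `y`, `z`.
#' @export
build_registry <- function(locators, variety = "unknown", plot = "unknown") {
  if (!nrow(locators)) stop("no locators")
  d <- as.matrix(dist(locators[, c("x", "y", "z")]))
  diag(d) <- Inf
  if (any(d < 1e-6)) stop("duplicate locators (double detection)")
  data.frame(variety = variety, plot = plot,
             plant_index = locators$plant_index,
             x = locators$x, y = locators$y, z = locators$z)
}

#' Localize every plant in a field
#'
#' Slices the localization layer out of the plant cloud, clusters it with
#' DBSCAN (fixed eps by default; `eps = "auto"` switches to the
#' density-derived radius of [auto_epsilon]), drops clusters smaller than
#' `min_cluster_size` (weed/noise guard), and registers one locator per
#' cluster.
#'
#' @param gp aligned plant [point_cloud].
#' @param layer localization height layer (m), default c(0.02, 0.06).
#' @param eps DBSCAN radius in meters (default 0.012) or `"auto"`.
#' @param min_pts DBSCAN MinPts.
#' @param min_cluster_size clusters below this size are discarded
#'   (default `2 * min_pts`).
#' @param variety,plot registry identity fields.
#' @return registry data.frame (see [build_registry]).
#' @export
locate_plants <- function(gp, layer = c(0.02, 0.06), eps = 0.012,
                          min_pts = 6L, min_cluster_size = 2L * min_pts,
                          variety = "unknown", plot = "unknown") {
  lay <- slice_layer(gp, layer)
  if (n_points(lay) == 0L) stop("localization layer is empty")
  if (identical(eps, "auto")) eps <- auto_epsilon(lay, min_pts)
  cl <- dbscan_clusters(lay, eps, min_pts)
  keep <- vapply(cl$clusters, length, integer(1)) >= min_cluster_size
  if (!any(keep)) stop("no cluster passes the size guard")
  loc <- localization_points(cl$clusters[keep], lay, layer)
  build_registry(loc, variety, plot)
}
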