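#' Point cloud container
#'
#' The universal currency of the pipeline: an n x 3 coordinate matrix in
#' meters (z up after scene alignment) with per-point RGB colors in
#' \[0, 1\] and optional per-point channels (unit normals, curvature in
#' \[0, 1\], integer instance labels). Label 0 is reserved for
#' "not a plant" (ground / unassigned); plants are labeled 1, 2, ...
#'
#' @param points numeric matrix (n x 3) of XYZ coordinates in meters.
#' @param colors numeric matrix (n x 3) of RGB in \[0, 1\], or `NULL` for
#'   mid-gray.
#' @param normals optional numeric matrix (n x 3) of unit normals.
#' @param curvatures optional numeric vector (n) of curvature in \[0, 1\].
#' @param labels optional integer vector (n) of instance labels (>= 0).
#'
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL, normals = NULL,
                        curvatures = NULL, labels = NULL) {
  points <- as_xyz_matrix(points, "points")
  n <- nrow(points)
  if (is.null(colors)) {
    colors <- matrix(0.5, n, 3)
  } else {
    colors <- as_xyz_matrix(colors, "colors")
  }
  pc <- structure(
    list(points = points, colors = colors, normals = NULL,
         curvatures = NULL, labels = NULL),
    class = "point_cloud"
  )
  if (!is.null(normals)) pc$normals <- as_xyz_matrix(normals, "normals")
  if (!is.null(curvatures)) pc$curvatures <- as.numeric(curvatures)
  if (!is.null(labels)) pc$labels <- as.integer(labels)
  validate_point_cloud(pc)
  pc
}

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  dimnames(x) <- NULL
  x
}

#' Validate a point cloud's invariants
#'
#' Checks channel lengths, color range, unit normals (to 1e-6) and
#' non-negative integer labels. Called by the constructor; exposed so that
#' readers and tests can re-assert after channel surgery.
#'
#' @param pc a `point_cloud`.
#' @return `pc`, invisibly; errors on violation.
#' @export
validate_point_cloud <- function(pc) {
  n <- nrow(pc$points)
  if (!all(is.finite(pc$points))) stop("non-finite coordinates")
  if (nrow(pc$colors) != n) stop("colors length mismatch")
  if (any(pc$colors < -1e-9) || any(pc$colors > 1 + 1e-9))
    stop("colors must lie in [0, 1]")
  if (!is.null(pc$normals)) {
    if (nrow(pc$normals) != n) stop("normals length mismatch")
    nrm <- sqrt(rowSums(pc$normals^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("normals must be unit length")
  }
  if (!is.null(pc$curvatures) && length(pc$curvatures) != n)
    stop("curvatures length mismatch")
  if (!is.null(pc$labels)) {
    if (length(pc$labels) != n) stop("labels length mismatch")
    if (any(pc$labels < 0L)) stop("labels must be >= 0")
  }
  invisible(pc)
}

#' Number of points in a cloud
#' @param pc a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(pc) nrow(pc$points)

#' Subset a point cloud by point index
#'
#' All channels are subset consistently. The indices of the retained points
#' in the parent cloud are recorded in the `source_indices` attribute so
#' that slices and filters can be mapped back to the full scene.
#'
#' @param pc a `point_cloud`.
#' @param idx integer or logical index vector.
#' @return a `point_cloud` with attribute `source_indices`.
#' @export
subset_cloud <- function(pc, idx) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- as.integer(idx)
  out <- pc
  out$points <- pc$points[idx, , drop = FALSE]
  out$colors <- pc$colors[idx, , drop = FALSE]
  if (!is.null(pc$normals)) out$normals <- pc$normals[idx, , drop = FALSE]
  if (!is.null(pc$curvatures)) out$curvatures <- pc$curvatures[idx]
  if (!is.null(pc$labels)) out$labels <- pc$labels[idx]
  parent <- attr(pc, "source_indices")
  attr(out, "source_indices") <- if (is.null(parent)) idx else parent[idx]
  out
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", n_points(x), "points")
  ch <- c(
    if (!is.null(x$normals)) "normals",
    if (!is.null(x$curvatures)) "curvatures",
    if (!is.null(x$labels)) "labels"
  )
  if (length(ch)) cat(" [", paste(ch, collapse = ", "), "]", sep = "")
  if (!is.null(x$labels)) {
    k <- sum(unique(x$labels) > 0L)
    cat(" —", k, "instances")
  }
  cat("\n")
  if (n_points(x) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2],
                rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}
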