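# Instance segmentation by dynamically constrained region growing.
# Each plant grows from its stem-layer seed points inside a private
# cylinder whose radius r_k = R_hk * tan(alpha) scales with that plant's
# measured region height R_hk. Neighbors join under three joint
# constraints: distance (|p-q| < delta), normal similarity
# (|n_p . n_q| >= tau_N) and constraint-region membership. Points reached
# by two or more plants in the same round are contested and settled
# afterwards by local plane distance and curvature consistency.

#' Growth parameter set
#'
#' Defaults follow the tuned values for seedling-stage cotton in
#' standardized breeding plots: eps 1.2 cm / MinPts 6 (localization
#' clustering), d 3.0 cm (locator cylinder), alpha 35 degrees (search
#' cone), delta 1.5 cm (growth distance), tau_N 0.85 (normal cosine).
#' The overlap-correction parameters (r_loc, gamma1, gamma2) and the
#' normal-estimation neighborhood are empirical.
#'
#' @param delta growth distance threshold (m).
#' @param tau_n normal-similarity cosine threshold in (0, 1\].
#' @param d_cyl locator cylinder radius (m) used for region height and
#'   seeds.
#' @param alpha cone half-angle (degrees) of the dynamic constraint.
#' @param r_loc neighborhood radius (m) for overlap attribution.
#' @param gamma1 curvature z-score bound for overlap attribution.
#' @param gamma2 plane-distance bound (m) for overlap attribution.
#' @param k_normals neighborhood size for normal/curvature estimation.
#' @param eps DBSCAN radius (m) for localization.
#' @param min_pts DBSCAN MinPts for localization.
#' @param layer localization height layer (m).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(delta = 0.015, tau_n = 0.85, d_cyl = 0.03,
                          alpha = 35, r_loc = 0.02, gamma1 = 2,
                          gamma2 = 0.005, k_normals = 20L, eps = 0.012,
                          min_pts = 6L, layer = c(0.02, 0.06)) {
  stopifnot(delta > 0, tau_n > 0, tau_n <= 1, gamma1 > 0, gamma2 > 0,
            alpha > 0, alpha < 90)
  structure(list(delta = delta, tau_n = tau_n, d_cyl = d_cyl, alpha = alpha,
                 r_loc = r_loc, gamma1 = gamma1, gamma2 = gamma2,
                 k_normals = as.integer(k_normals), eps = eps,
                 min_pts = as.integer(min_pts), layer = layer),
            class = "growth_params")
}

#' Estimate per-point normals and curvature
#'
#' Unit normal = eigenvector of the smallest eigenvalue of the local
#' covariance over the k-nearest neighborhood (the point included);
#' curvature = lambda0 / (lambda0 + lambda1 + lambda2) in \[0, 1/3\].
#' Normals are sign-normalized to the +z hemisphere; downstream
#' comparisons use |cosine| so the residual sign ambiguity is harmless.
#'
#' @param cloud a [point_cloud].
#' @param k neighborhood size (>= 3, < number of points).
#' @return the cloud with `normals` and `curvatures` filled in.
#' @export
estimate_normals_curvature <- function(cloud, k = 20L) {
  n <- n_points(cloud)
  if (k < 3L) stop("k must be >= 3")
  if (n <= k) stop("need more than k points")
  nn <- RANN::nn2(cloud$points, k = k + 1L)
  res <- cpp_normals_curvature(cloud$points, nn$nn.idx)
  out <- cloud
  nrm <- res[, 1:3, drop = FALSE]
  out$normals <- nrm / sqrt(rowSums(nrm^2))
  out$curvatures <- res[, 4]
  out
}

#' Plant region height
#'
#' Maximum z among the points whose horizontal distance to the
#' localization point is at most `d_cyl` (the cylindrical envelope around
#' the stem).
#'
#' @param gp plant [point_cloud].
#' @param a_pk localization point, numeric (x, y, z).
#' @param d_cyl cylinder radius (m).
#' @return region height R_hk (m).
#' @export
region_height <- function(gp, a_pk, d_cyl = 0.03) {
  dx <- gp$points[, 1] - a_pk[1]
  dy <- gp$points[, 2] - a_pk[2]
  inside <- dx * dx + dy * dy <= d_cyl^2
  if (!any(inside)) stop("no points inside the locator cylinder")
  max(gp$points[inside, 3])
}

#' Per-plant dynamic constraint region
#'
#' Cylinder centered on the localization point with base radius
#' `r_k = r_hk * tan(alpha)` and floor `z_min`; membership is
#' `(x - x_k)^2 + (y - y_k)^2 <= r_k^2 & z >= z_min`.
#'
#' @param a_pk localization point (x, y, z).
#' @param r_hk region height (m).
#' @param alpha cone half-angle in degrees, 0 < alpha < 90.
#' @param z_min region floor (m), minimum z of the region of interest.
#' @return object of class `constraint_region`.
#' @export
make_constraint_region <- function(a_pk, r_hk, alpha = 35, z_min = 0) {
  if (!(alpha > 0 && alpha < 90)) stop("alpha must be in (0, 90) degrees")
  structure(list(a_pk = as.numeric(a_pk)[1:3], r_hk = r_hk, alpha = alpha,
                 r_k = r_hk * tan(alpha * pi / 180), z_min = z_min),
            class = "constraint_region")
}

#' Constraint-region membership test
#' @param region a [make_constraint_region] result.
#' @param pts m x 3 coordinate matrix.
#' @return logical vector.
#' @export
region_contains <- function(region, pts) {
  pts <- as_xyz_matrix(pts, "pts")
  dx <- pts[, 1] - region$a_pk[1]
  dy <- pts[, 2] - region$a_pk[2]
  dx * dx + dy * dy <= region$r_k^2 & pts[, 3] >= region$z_min
}

#' Grow plant instances from seed points
#'
#' Breadth-first growth in plant-synchronous rounds: in every round each
#' plant's frontier claims the unassigned neighbors that satisfy the three
#' constraints; points claimed by a single plant are labeled and join its
#' frontier, points claimed by several plants in the same round become
#' contested and are frozen (their claimant sets are kept for
#' [resolve_overlaps]). Round-robin discovery makes the result independent
#' of plant order and of point order.
#'
#' @param gp plant [point_cloud] with normals.
#' @param seeds list: element k holds the seed point indices of plant k.
#' @param regions list of [make_constraint_region] objects, element k for
#'   plant k.
#' @param params a [growth_params] object.
#' @return object of class `instance_labeling`: `labels` (0 = unassigned),
#'   `contested` (indices), `claims` (list of claimant plant ids per
#'   contested point).
#' @export
grow_instances <- function(gp, seeds, regions, params = growth_params()) {
  if (is.null(gp$normals)) stop("gp must carry normals")
  K <- length(regions)
  if (length(seeds) != K) stop("seeds and regions must align")
  n <- n_points(gp)
  labels0 <- integer(n)
  for (k in seq_len(K)) {
    if (!length(seeds[[k]])) stop("empty seeds for plant ", k)
    labels0[seeds[[k]]] <- k
  }
  centers <- t(vapply(regions, function(r) r$a_pk[1:2], numeric(2)))
  radius2 <- vapply(regions, function(r) r$r_k^2, numeric(1))
  z_min <- min(vapply(regions, function(r) r$z_min, numeric(1)))
  res <- cpp_grow_instances(gp$points, gp$normals, labels0, centers,
                            radius2, z_min, params$delta, params$tau_n)
  structure(list(labels = res$labels, contested = res$contested,
                 claims = res$claims),
            class = "instance_labeling")
}

#' @export
print.instance_labeling <- function(x, ...) {
  cat("instance_labeling:", length(x$labels), "points,",
      length(unique(x$labels[x$labels > 0])), "instances,",
      sum(x$labels == 0), "unassigned,",
      length(x$contested), "contested\n")
  invisible(x)
}

# deterministic robust plane fit: total least squares with one trimmed
# refit (residuals beyond 2.5x the median absolute residual dropped)
fit_plane_robust <- function(pts) {
  fit <- function(p) {
    ctr <- colMeans(p)
    ev <- eigen(crossprod(sweep(p, 2, ctr)), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    c(nrm, -sum(nrm * ctr))
  }
  cf <- fit(pts)
  res <- abs(pts %*% cf[1:3] + cf[4])
  tol <- 2.5 * max(median(res), 1e-6)
  keep <- res <= tol
  if (sum(keep) >= 3 && sum(keep) < nrow(pts)) cf <- fit(pts[keep, , drop = FALSE])
  cf
}

#' Resolve contested (overlap) points
#'
#' For each contested point q and each claimant plant k: collect the
#' labeled points of k within `r_loc` of q, keep the normal-consistent
#' ones (|n_p . n_q| >= tau_N) as the fitting set F, fit a robust plane to
#' F, and accept k when the point-to-plane distance is below `gamma2` and
#' the point's curvature lies within `gamma1` standard deviations of F's
#' mean curvature. The point goes to the accepting plant with the smallest
#' plane distance (ties to the smaller plant id); if no plant accepts it
#' stays unassigned.
#'
#' @param gp plant [point_cloud] with normals and curvatures.
#' @param labeling an [grow_instances] result.
#' @param params a [growth_params] object.
#' @return an `instance_labeling` with empty `contested`.
#' @export
resolve_overlaps <- function(gp, labeling, params = growth_params()) {
  if (!length(labeling$contested)) {
    labeling$claims <- list()
    return(labeling)
  }
  if (is.null(gp$curvatures)) stop("gp must carry curvatures")
  labels <- labeling$labels
  cont <- labeling$contested
  nbrs <- cpp_radius_neighbors(gp$points, gp$points[cont, , drop = FALSE],
                               params$r_loc)
  new_lab <- integer(length(cont))
  for (i in seq_along(cont)) {
    q <- cont[i]
    nb <- setdiff(nbrs[[i]], q)
    if (!length(nb)) next
    ndot <- abs(gp$normals[nb, , drop = FALSE] %*% gp$normals[q, ])
    best_k <- 0L
    best_d <- Inf
    for (k in labeling$claims[[i]]) {
      Fk <- nb[labels[nb] == k & ndot >= params$tau_n]
      if (length(Fk) < 3L) next
      cf <- fit_plane_robust(gp$points[Fk, , drop = FALSE])
      d <- abs(sum(cf[1:3] * gp$points[q, ]) + cf[4])
      mu <- mean(gp$curvatures[Fk])
      # absolute floor: near-zero support variance (flat blades) must not
      # reject every candidate outright
      sg <- max(sd(gp$curvatures[Fk]), 0.01)
      if (d < params$gamma2 && abs(gp$curvatures[q] - mu) <= params$gamma1 * sg
          && d < best_d) {
        best_d <- d
        best_k <- k
      }
    }
    new_lab[i] <- best_k
  }
  labels[cont] <- new_lab
  structure(list(labels = labels, contested = integer(0), claims = list()),
            class = "instance_labeling")
}

#' Segment a plant population end to end
#'
#' Orchestrates the dynamic-constraint segmentation for every registered
#' plant: estimates normals/curvature if absent, measures each plant's
#' region height in its locator cylinder, builds the constraint regions
#' (floor at the minimum z of the cloud), grows all plants in synchronous
#' rounds from their stem seed points, and settles contested points.
#' Plants whose locator cylinder holds no points are skipped with a
#' warning. Deterministic for fixed input.
#'
#' @param gp preprocessed plant [point_cloud].
#' @param registry data.frame from [locate_plants] / [build_registry].
#' @param params a [growth_params] object.
#' @return an `instance_labeling`; label values are registry plant indices.
#' @export
segment_population <- function(gp, registry, params = growth_params()) {
  if (is.null(gp$normals) || is.null(gp$curvatures))
    gp <- estimate_normals_curvature(gp, params$k_normals)
  registry <- registry[order(registry$plant_index), , drop = FALSE]
  z_min <- min(gp$points[, 3])
  regions <- list()
  seeds <- list()
  kept <- integer(0)
  for (r in seq_len(nrow(registry))) {
    a_pk <- c(registry$x[r], registry$y[r], registry$z[r])
    dx <- gp$points[, 1] - a_pk[1]
    dy <- gp$points[, 2] - a_pk[2]
    in_cyl <- dx * dx + dy * dy <= params$d_cyl^2
    seed <- which(in_cyl & gp$points[, 3] <= a_pk[3])
    if (!any(in_cyl) || !length(seed)) {
      warning("plant ", registry$plant_index[r],
              ": locator cylinder empty, skipped")
      next
    }
    r_hk <- max(gp$points[in_cyl, 3])
    kept <- c(kept, r)
    regions[[length(regions) + 1L]] <-
      make_constraint_region(a_pk, r_hk, params$alpha, z_min)
    seeds[[length(seeds) + 1L]] <- seed
  }
  if (!length(kept)) stop("no plant has seed points")
  lab <- grow_instances(gp, seeds, regions, params)
  lab <- resolve_overlaps(gp, lab, params)
  # map internal ids 1..K back to registry plant indices
  ids <- registry$plant_index[kept]
  remap <- c(0L, as.integer(ids))
  lab$labels <- remap[lab$labels + 1L]
  lab$regions <- setNames(regions, ids)
  lab
}
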