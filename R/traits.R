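# Per-plant trait extraction. Heights are differences against a local
# ground datum: FCNH = z_fn - z_gd (cotyledon node above ground) and
# PH = z_msv - z_gd (apex above ground). Leaves are low-curvature,
# normal-consistent, planarity-checked point clusters; each leaf's area is
# the area of a support-trimmed height-field mesh over its principal plane.

#' Trait-extraction parameter set
#'
#' @param datum_radius radius (m) of local ground used for the datum.
#' @param curv_max curvature threshold separating blades from tubes.
#' @param leaf_radius connectivity radius (m) for leaf clustering.
#' @param leaf_tau normal-cosine threshold for leaf clustering.
#' @param min_leaf_points smallest accepted leaf cluster.
#' @param plane_tol planarity tolerance (m) for leaf verification and leaf
#'   removal during node detection.
#' @param stem_radial_tol radial distance (m) beyond which residual points
#'   count as branch material.
#' @param node_gap_tol maximum stem/branch line gap (m) for a node.
#' @param k_normals neighborhood for normals/curvature when absent.
#' @param curv_k larger neighborhood used to classify blades vs tubes
#'   (curvature contrast between laminae and stems grows with the
#'   neighborhood, up to the lamina size).
#' @return object of class `trait_params`.
#' @export
trait_params <- function(datum_radius = 0.15, curv_max = 0.05,
                         leaf_radius = 0.008, leaf_tau = 0.80,
                         min_leaf_points = 30L, plane_tol = 0.004,
                         stem_radial_tol = 0.009, node_gap_tol = 0.01,
                         k_normals = 20L, curv_k = 40L) {
  structure(list(datum_radius = datum_radius, curv_max = curv_max,
                 leaf_radius = leaf_radius, leaf_tau = leaf_tau,
                 min_leaf_points = as.integer(min_leaf_points),
                 plane_tol = plane_tol, stem_radial_tol = stem_radial_tol,
                 node_gap_tol = node_gap_tol,
                 k_normals = as.integer(k_normals),
                 curv_k = as.integer(curv_k),
                 smooth_passes = 2L),
            class = "trait_params")
}

#' Local ground datum under a plant
#'
#' Median z of the ground points within `radius` (horizontal) of the
#' plant's localization point; falls back to the global ground median
#' (with a warning) when fewer than 10 local points exist.
#'
#' @param gs ground-surface [point_cloud].
#' @param a_pk localization point (x, y, ...).
#' @param radius horizontal search radius (m).
#' @return list with `z_gd` and `flag` ("" or "global_datum").
#' @export
ground_datum <- function(gs, a_pk, radius = 0.15) {
  dx <- gs$points[, 1] - a_pk[1]
  dy <- gs$points[, 2] - a_pk[2]
  local <- dx * dx + dy * dy <= radius^2
  if (sum(local) >= 10L) {
    list(z_gd = median(gs$points[local, 3]), flag = "")
  } else {
    warning("fewer than 10 local ground points; using global ground median")
    list(z_gd = median(gs$points[, 3]), flag = "global_datum")
  }
}

#' Plant height
#'
#' PH = max z of the plant minus the ground datum.
#'
#' @param plant plant [point_cloud] (non-empty).
#' @param z_gd ground datum (m).
#' @return height in meters.
#' @export
plant_height <- function(plant, z_gd) {
  if (n_points(plant) == 0L) stop("empty plant")
  max(plant$points[, 3]) - z_gd
}

#' Segment the leaves of a plant
#'
#' Three stages. (1) Blade detection: after `smooth_passes` extra
#' bilateral passes (blade/tube curvature contrast sharpens as noise
#' shrinks), the low-curvature points — blades are locally planar, tubes
#' are not — are grouped into connected clusters under joint proximity and
#' normal agreement; clusters below `min_leaf_points` are dropped and each
#' survivor must be planarity-verified (a robust plane captures >= 80% of
#' it within `plane_tol`). (2) Completion: each cluster grows outward to
#' the blade edges that the curvature threshold missed — an unassigned
#' point joins when it touches the cluster, lies within `2 * plane_tol` of
#' the cluster's plane, and its normal agrees with the plane normal (stem
#' and petiole points embedded in the blade plane have normals
#' perpendicular to it, so tubes are not swallowed). (3) Each cluster is
#' returned as indices into the input cloud; the smoothed copy used for
#' detection is attached as attribute `cloud` for area measurement.
#'
#' @param plant plant [point_cloud].
#' @param params a [trait_params] object.
#' @return list of integer index vectors (into the plant cloud), one per
#'   leaf; may be empty. Attribute `cloud` holds the smoothed plant.
#' @export
segment_leaves <- function(plant, params = trait_params()) {
  n <- n_points(plant)
  k_eff <- min(params$curv_k, n - 1L)
  if (k_eff < 3L || n < params$min_leaf_points) return(list())
  sm <- plant
  # normals estimated once from the raw coordinates steer every smoothing
  # pass (a fixed projection direction flattens blades more consistently
  # than re-estimating on partially smoothed points)
  sm$normals <- NULL
  sm$curvatures <- NULL
  if (params$smooth_passes > 0 && n > 21L)
    for (i in seq_len(params$smooth_passes))
      sm <- bilateral_smooth(sm, k = 20L)
  # blade/tube contrast is estimated at the wider curv_k neighborhood
  sm <- estimate_normals_curvature(sm, k_eff)
  cand <- which(sm$curvatures < params$curv_max)
  if (!length(cand)) {
    out <- list()
    attr(out, "cloud") <- sm
    return(out)
  }
  comp <- cpp_normal_components(sm$points[cand, , drop = FALSE],
                                sm$normals[cand, , drop = FALSE],
                                params$leaf_radius, params$leaf_tau)
  labs <- integer(n)
  nk <- 0L
  for (k in seq_len(max(comp))) {
    idx <- cand[comp == k]
    if (length(idx) < params$min_leaf_points) next
    p <- sm$points[idx, , drop = FALSE]
    cf <- fit_plane_robust(p)
    res <- abs(p %*% cf[1:3] + cf[4])
    # blades are planar (inlier fraction and rms) and two-dimensional
    # (in-plane aspect); smoothed stem segments fail both
    ev <- eigen(crossprod(sweep(p, 2, colMeans(p))), symmetric = TRUE,
                only.values = TRUE)$values
    if (mean(res <= params$plane_tol) >= 0.8 &&
        sqrt(mean(res^2)) <= 0.5 * params$plane_tol &&
        ev[2] / ev[1] >= 0.15) {
      nk <- nk + 1L
      labs[idx] <- nk
    }
  }
  if (nk > 0L) labs <- expand_leaf_clusters(sm, labs, nk, params)
  out <- lapply(seq_len(nk), function(k) which(labs == k))
  attr(out, "cloud") <- sm
  out
}

# grow blade clusters to their edges: proximity + plane membership +
# normal agreement with the cluster plane
expand_leaf_clusters <- function(sm, labs, nk, params) {
  for (it in 1:6) {
    planes <- lapply(seq_len(nk), function(k)
      fit_plane_robust(sm$points[labs == k, , drop = FALSE]))
    un <- which(labs == 0L)
    if (!length(un)) break
    nb <- cpp_radius_neighbors(sm$points, sm$points[un, , drop = FALSE],
                               params$leaf_radius)
    changed <- FALSE
    for (i in seq_along(un)) {
      q <- un[i]
      ks <- unique(labs[nb[[i]]])
      ks <- ks[ks > 0L & ks != labs[q]]
      best_k <- 0L
      best_r <- Inf
      for (k in ks) {
        cf <- planes[[k]]
        r <- abs(sum(cf[1:3] * sm$points[q, ]) + cf[4])
        if (r <= 2 * params$plane_tol &&
            abs(sum(cf[1:3] * sm$normals[q, ])) >= params$leaf_tau &&
            r < best_r) {
          best_r <- r
          best_k <- k
        }
      }
      if (best_k > 0L) {
        labs[q] <- best_k
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labs
}

#' Leaf area from a support-trimmed height-field mesh
#'
#' The cluster is projected onto its principal (PCA) plane and meshed on a
#' regular grid: node heights are kernel-weighted means of nearby point
#' offsets (which also suppresses sensor noise), and only cells whose
#' smoothed point count reaches half the median occupied-cell count are
#' kept — under noise the half-density contour sits on the true boundary,
#' so the support trim is unbiased. The area is the summed area of the two
#' triangles per kept cell. Falls back to the projected convex-hull area
#' (flagged) if the grid degenerates.
#'
#' @param cluster a [point_cloud] with at least 30 points (one leaf).
#' @param cell grid spacing (m); default 2.5x the median point spacing,
#'   clamped to \[1.5, 10\] mm.
#' @return list with `area` (m^2) and `flag` ("" or "hull_fallback").
#' @export
leaf_area <- function(cluster, cell = NULL) {
  pts <- if (inherits(cluster, "point_cloud")) cluster$points else
    as_xyz_matrix(cluster, "cluster")
  m <- nrow(pts)
  if (m < 30L) stop("leaf cluster must have at least 30 points")
  ctr <- colMeans(pts)
  ev <- eigen(crossprod(sweep(pts, 2, ctr)), symmetric = TRUE)
  uvw <- sweep(pts, 2, ctr) %*% ev$vectors  # u, v in-plane; w offset
  if (is.null(cell)) {
    # ~6 points per cell in expectation (median NN spacing is about half
    # the mean lattice spacing), so empty interior cells are rare and the
    # smoothed occupancy is stable
    nn <- RANN::nn2(uvw[, 1:2], k = 2L)
    cell <- max(0.002, min(0.02, 5 * median(nn$nn.dists[, 2])))
  }
  ur <- range(uvw[, 1]); vr <- range(uvw[, 2])
  nx <- ceiling((ur[2] - ur[1]) / cell) + 1L
  nyv <- ceiling((vr[2] - vr[1]) / cell) + 1L
  if (nx < 2L || nyv < 2L) return(leaf_area_hull(uvw))
  ix <- pmin(floor((uvw[, 1] - ur[1]) / cell) + 1L, nx)
  iy <- pmin(floor((uvw[, 2] - vr[1]) / cell) + 1L, nyv)
  counts <- matrix(0, nx, nyv)
  tab <- table((iy - 1L) * nx + ix)
  counts[as.integer(names(tab))] <- tab
  sm3 <- function(mm) {
    p <- matrix(0, nrow(mm) + 2L, ncol(mm) + 2L)
    p[2:(nrow(mm) + 1L), 2:(ncol(mm) + 1L)] <- mm
    (p[1:nrow(mm), 1:ncol(mm)] + p[1:nrow(mm), 2:(ncol(mm) + 1L)] +
       p[1:nrow(mm), 3:(ncol(mm) + 2L)] +
       p[2:(nrow(mm) + 1L), 1:ncol(mm)] + mm +
       p[2:(nrow(mm) + 1L), 3:(ncol(mm) + 2L)] +
       p[3:(nrow(mm) + 2L), 1:ncol(mm)] +
       p[3:(nrow(mm) + 2L), 2:(ncol(mm) + 1L)] +
       p[3:(nrow(mm) + 2L), 3:(ncol(mm) + 2L)]) / 9
  }
  smc <- sm3(counts)
  # plateau (interior) density from the upper quantile of occupied cells:
  # boundary and noise-fringe cells populate the lower quantiles, so the
  # half-plateau support contour stays anchored to the true edge
  thresh <- 0.5 * quantile(smc[counts > 0], 0.85, names = FALSE)
  keep <- which(smc >= thresh, arr.ind = TRUE)
  if (!nrow(keep)) return(leaf_area_hull(uvw))

  # node heights: kernel-weighted mean of nearby offsets
  node_u <- ur[1] + (0:(nx)) * cell
  node_v <- vr[1] + (0:(nyv)) * cell
  need <- unique(rbind(keep, keep + matrix(c(1, 0), nrow(keep), 2, TRUE),
                       keep + matrix(c(0, 1), nrow(keep), 2, TRUE),
                       keep + matrix(c(1, 1), nrow(keep), 2, TRUE)))
  nodes <- cbind(node_u[need[, 1]], node_v[need[, 2]])
  nnn <- RANN::nn2(uvw[, 1:2], nodes, k = min(12L, m))
  wts <- exp(-nnn$nn.dists^2 / (2 * cell^2))
  hz <- rowSums(wts * matrix(uvw[nnn$nn.idx, 3], nrow(nodes))) / rowSums(wts)
  node_key <- (need[, 2] - 1L) * (nx + 1L) + need[, 1]
  hfun <- setNames(hz, node_key)

  tri_area <- function(p1, p2, p3) {
    v1 <- p2 - p1; v2 <- p3 - p1
    sqrt(pmax(
      (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2])^2 +
        (v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3])^2 +
        (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])^2, 0)) / 2
  }
  keyof <- function(i, j) as.character((j - 1L) * (nx + 1L) + i)
  corner <- function(i, j) {
    cbind(node_u[i], node_v[j], hfun[keyof(i, j)])
  }
  i <- keep[, 1]; j <- keep[, 2]
  p00 <- corner(i, j); p10 <- corner(i + 1L, j)
  p01 <- corner(i, j + 1L); p11 <- corner(i + 1L, j + 1L)
  area <- sum(tri_area(p00, p10, p11)) + sum(tri_area(p00, p11, p01))
  list(area = area, flag = "")
}

leaf_area_hull <- function(uvw) {
  h <- chull(uvw[, 1], uvw[, 2])
  x <- uvw[h, 1]; y <- uvw[h, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(area = a, flag = "hull_fallback")
}

# robust principal line through a point set: PCA direction with one
# trimmed refit; returns list(point, dir)
fit_line_robust <- function(pts) {
  fit <- function(p) {
    ctr <- colMeans(p)
    ev <- eigen(crossprod(sweep(p, 2, ctr)), symmetric = TRUE)
    list(point = ctr, dir = ev$vectors[, 1])
  }
  ln <- fit(pts)
  d <- sweep(pts, 2, ln$point)
  proj <- d %*% ln$dir
  res <- sqrt(pmax(rowSums(d^2) - proj^2, 0))
  keep <- res <= 2.5 * max(median(res), 1e-6)
  if (sum(keep) >= 3 && sum(keep) < nrow(pts)) ln <- fit(pts[keep, , drop = FALSE])
  ln
}

# closest-approach midpoint between two 3D lines; NULL if near-parallel
line_gap_midpoint <- function(l1, l2) {
  w0 <- l1$point - l2$point
  a <- 1; b <- sum(l1$dir * l2$dir); c <- 1
  d <- sum(l1$dir * w0); e <- sum(l2$dir * w0)
  den <- a * c - b * b
  if (den < 1e-9) return(NULL)
  s <- (b * e - c * d) / den
  t <- (a * e - b * d) / den
  p1 <- l1$point + s * l1$dir
  p2 <- l2$point + t * l2$dir
  list(gap = sqrt(sum((p1 - p2)^2)), mid = (p1 + p2) / 2)
}

#' Detect the cotyledon node height of one plant
#'
#' A robust near-vertical line is fit to the leaf-free residual (blades
#' removed as plane-fit-verified leaf clusters); all points lying off the
#' stem axis — petioles plus the blade material continuing each petiole's
#' direction — are clustered into branch segments. Segments that hug the
#' axis (radial extent below `stem_radial_tol` + 8 mm: stem skin) or run
#' near-vertical (stem fragments) are rejected; each accepted segment's
#' robust line is intersected with the stem line (closest-approach
#' midpoint, accepted when the line gap is below `node_gap_tol`). The
#' cotyledon node is the mean z of the lowest intersections within 5 mm of
#' the minimum — cotyledons insert as an opposite pair at a single node,
#' so averaging the pair cancels per-petiole noise. Without any accepted
#' branch, the lowest z at which the residual points' lateral spread
#' breaks outward is returned with a low-confidence flag.
#'
#' @param plant plant [point_cloud] with at least 200 points.
#' @param params a [trait_params] object.
#' @return list with `z_fn` (m), `confidence` ("ok" or "low"), and
#'   `nodes` (z of every accepted intersection).
#' @export
detect_cotyledon_node <- function(plant, params = trait_params()) {
  if (n_points(plant) < 200L) stop("plant too small for node detection")
  leaves <- segment_leaves(plant, params)
  smp <- attr(leaves, "cloud")
  if (is.null(smp)) smp <- plant
  leaf_idx <- unlist(leaves)
  resid <- setdiff(seq_len(n_points(plant)), leaf_idx)
  rp <- smp$points[resid, , drop = FALSE]

  # stem axis: iterate a vertical-line fit on near-axis points
  axis_xy <- c(median(rp[, 1]), median(rp[, 2]))
  stem_line <- list(point = c(axis_xy, mean(rp[, 3])), dir = c(0, 0, 1))
  for (it in 1:3) {
    d <- sweep(rp, 2, stem_line$point)
    proj <- d %*% stem_line$dir
    rad <- sqrt(pmax(rowSums(d^2) - proj^2, 0))
    near <- rad <= max(params$stem_radial_tol, quantile(rad, 0.3))
    if (sum(near) < 10) break
    ln <- fit_line_robust(rp[near, , drop = FALSE])
    if (abs(ln$dir[3]) < cos(30 * pi / 180)) break  # keep near-vertical
    if (ln$dir[3] < 0) ln$dir <- -ln$dir
    stem_line <- ln
  }

  # branch material: every point (blades included, for lever arm) off the
  # stem axis but within reach of an insertion
  ap <- smp$points
  da <- sweep(ap, 2, stem_line$point)
  pra <- da %*% stem_line$dir
  rada <- sqrt(pmax(rowSums(da^2) - pra^2, 0))
  branchy <- which(rada > params$stem_radial_tol & rada < 0.06)
  nodes <- numeric(0)
  if (length(branchy) >= 6L) {
    bp <- ap[branchy, , drop = FALSE]
    comp <- cpp_dbscan(bp, eps = 0.012, min_pts = 1L)
    for (k in seq_len(max(comp))) {
      seg <- which(comp == k)
      if (length(seg) < 6L) next
      if (max(rada[branchy[seg]]) < params$stem_radial_tol + 0.008)
        next  # stem skin: no real radial extent
      bl <- fit_line_robust(bp[seg, , drop = FALSE])
      if (abs(bl$dir[3]) > 0.9) next  # near-vertical: stem fragment
      hit <- line_gap_midpoint(stem_line, bl)
      if (!is.null(hit) && hit$gap < params$node_gap_tol)
        nodes <- c(nodes, hit$mid[3])
    }
  }
  if (length(nodes)) {
    low <- nodes[nodes <= min(nodes) + 0.005]
    return(list(z_fn = mean(low), confidence = "ok", nodes = sort(nodes)))
  }
  rad <- sqrt(pmax(rowSums(sweep(rp, 2, stem_line$point)^2) -
                     (sweep(rp, 2, stem_line$point) %*% stem_line$dir)^2, 0))
  # fallback: lowest z where lateral spread breaks outward
  zb <- seq(min(rp[, 3]), max(rp[, 3]), by = 0.01)
  if (length(zb) > 2) {
    spread <- vapply(seq_len(length(zb) - 1L), function(b) {
      sel <- rp[, 3] >= zb[b] & rp[, 3] < zb[b + 1L]
      if (sum(sel) < 3) return(NA_real_)
      max(rad[sel])
    }, numeric(1))
    base <- median(spread, na.rm = TRUE)
    brk <- which(!is.na(spread) & spread > 2 * base)
    if (length(brk))
      return(list(z_fn = zb[brk[1]], confidence = "low", nodes = numeric(0)))
  }
  list(z_fn = min(rp[, 3]), confidence = "low", nodes = numeric(0))
}

#' Extract trait records for every registered plant
#'
#' One row per registry plant: FCNH = z_fn - z_gd, PH = z_msv - z_gd
#' (apex minus ground datum; the node-referenced variant is reported as
#' `ph_from_node_m`), leaf count and per-leaf areas. Per-plant failures
#' are flagged in the `flags` column, never aborting the batch.
#'
#' @param labeled an `instance_labeling` over `gp` (labels = plant index).
#' @param gp plant [point_cloud].
#' @param gs ground-surface [point_cloud].
#' @param registry registry data.frame (see [build_registry]).
#' @param params a [trait_params] object.
#' @return data.frame with columns variety, plot, plant_index, fcnh_m,
#'   ph_m, ph_from_node_m, leaf_count, leaf_area_total_m2, z_gd, z_fn,
#'   z_msv, flags; attribute `leaf_areas` holds the per-leaf areas.
#' @export
extract_traits <- function(labeled, gp, gs, registry,
                           params = trait_params()) {
  labels <- as_label_vector(labeled)
  if (is.null(gp$normals) || is.null(gp$curvatures))
    gp <- estimate_normals_curvature(gp, params$k_normals)
  rows <- vector("list", nrow(registry))
  leaf_areas <- vector("list", nrow(registry))
  for (r in seq_len(nrow(registry))) {
    k <- registry$plant_index[r]
    flags <- character(0)
    idx <- which(labels == k)
    a_pk <- c(registry$x[r], registry$y[r], registry$z[r])
    gd <- withCallingHandlers(
      ground_datum(gs, a_pk, params$datum_radius),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nzchar(gd$flag)) flags <- c(flags, gd$flag)
    if (!length(idx)) {
      rows[[r]] <- data.frame(
        variety = registry$variety[r], plot = registry$plot[r],
        plant_index = k, fcnh_m = NA_real_, ph_m = NA_real_,
        ph_from_node_m = NA_real_, leaf_count = NA_integer_,
        leaf_area_total_m2 = NA_real_, z_gd = gd$z_gd, z_fn = NA_real_,
        z_msv = NA_real_, flags = "no_points")
      next
    }
    plant <- subset_cloud(gp, idx)
    z_msv <- max(plant$points[, 3])
    ph <- z_msv - gd$z_gd
    node <- tryCatch(detect_cotyledon_node(plant, params),
                     error = function(e) NULL)
    if (is.null(node)) {
      z_fn <- NA_real_
      flags <- c(flags, "node_failed")
    } else {
      z_fn <- node$z_fn
      if (node$confidence == "low") flags <- c(flags, "node_low_confidence")
    }
    leaves <- tryCatch(segment_leaves(plant, params), error = function(e) list())
    smp <- attr(leaves, "cloud")
    if (is.null(smp)) smp <- plant
    la <- numeric(0)
    for (lf in leaves) {
      est <- tryCatch(leaf_area(subset_cloud(smp, lf)),
                      error = function(e) NULL)
      if (is.null(est)) {
        flags <- c(flags, "leaf_area_failed")
      } else {
        la <- c(la, est$area)
        if (nzchar(est$flag)) flags <- c(flags, est$flag)
      }
    }
    leaf_areas[[r]] <- la
    rows[[r]] <- data.frame(
      variety = registry$variety[r], plot = registry$plot[r],
      plant_index = k, fcnh_m = if (is.na(z_fn)) NA_real_ else z_fn - gd$z_gd,
      ph_m = ph,
      ph_from_node_m = if (is.na(z_fn)) NA_real_ else z_msv - z_fn,
      leaf_count = length(la), leaf_area_total_m2 = sum(la),
      z_gd = gd$z_gd, z_fn = z_fn, z_msv = z_msv,
      flags = paste(unique(flags), collapse = ";"))
  }
  out <- do.call(rbind, rows)
  attr(out, "leaf_areas") <- leaf_areas
  out
}
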