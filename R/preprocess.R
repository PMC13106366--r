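# Scene cleanup: RANSAC ground-plane detection, quaternion alignment of the
# ground normal to +z, statistical and bilateral denoising, RGB -> HSI, and
# the hue-enhanced cloth simulation filter (HCSF) separating ground-surface
# (GS) from ground-plant (GP) points.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from a unit quaternion
#'
#' Standard expansion for q = (w, x, y, z):
#' rows (1-2y^2-2z^2, 2xy-2zw, 2xz+2yw), (2xy+2zw, 1-2x^2-2z^2, 2yz-2xw),
#' (2xz-2yw, 2yz+2xw, 1-2x^2-2y^2).
#'
#' @param q numeric length-4 quaternion (w, x, y, z), unit norm.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * y^2 - 2 * z^2, 2 * x * y - 2 * z * w, 2 * x * z + 2 * y * w,
    2 * x * y + 2 * z * w, 1 - 2 * x^2 - 2 * z^2, 2 * y * z - 2 * x * w,
    2 * x * z - 2 * y * w, 2 * y * z + 2 * x * w, 1 - 2 * x^2 - 2 * y^2
  ), 3, 3, byrow = TRUE)
}

#' Fit the ground plane by RANSAC
#'
#' Random minimal triples propose planes; the plane with the most points
#' within `dist_tol` wins and is refit by total least squares on its
#' inliers. The normal is oriented toward the crop side: positive mean
#' signed distance of the non-inlier points (toward +z when every point is
#' an inlier).
#'
#' @param cloud a [point_cloud] (>= 3 non-collinear points).
#' @param dist_tol inlier distance tolerance (m).
#' @param iters number of RANSAC proposals.
#' @param seed RNG seed.
#' @return object of class `ground_plane`: `coeffs` (a, b, c, d) with unit
#'   normal and `inlier_indices`.
#' @export
fit_ground_plane <- function(cloud, dist_tol = 0.01, iters = 200L, seed = 1L) {
  pts <- cloud$points
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to fit a plane")
  set.seed(seed)
  best_cnt <- -1L
  best_nrm <- NULL
  best_d <- NA_real_
  for (it in seq_len(iters)) {
    tri <- sample.int(n, 3L)
    v1 <- pts[tri[2], ] - pts[tri[1], ]
    v2 <- pts[tri[3], ] - pts[tri[1], ]
    nrm <- cross3(v1, v2)
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12) next
    nrm <- nrm / len
    d <- -sum(nrm * pts[tri[1], ])
    cnt <- sum(abs(pts %*% nrm + d) <= dist_tol)
    if (cnt > best_cnt) {
      best_cnt <- cnt
      best_nrm <- nrm
      best_d <- d
    }
  }
  if (is.null(best_nrm)) stop("degenerate (collinear) plane support")
  inl <- which(abs(pts %*% best_nrm + best_d) <= dist_tol)
  # least-squares refit: centroid + smallest-variance direction
  ctr <- colMeans(pts[inl, , drop = FALSE])
  cm <- crossprod(sweep(pts[inl, , drop = FALSE], 2, ctr))
  ev <- eigen(cm, symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  d <- -sum(nrm * ctr)
  out <- which(abs(pts %*% nrm + d) > dist_tol)
  flip <- if (length(out)) mean(pts[out, , drop = FALSE] %*% nrm + d) < 0
          else nrm[3] < 0 || (nrm[3] == 0 && (nrm[2] < 0 || (nrm[2] == 0 && nrm[1] < 0)))
  if (flip) {
    nrm <- -nrm
    d <- -d
  }
  inl <- which(abs(pts %*% nrm + d) <= dist_tol)
  structure(list(coeffs = c(nrm, d), inlier_indices = inl),
            class = "ground_plane")
}

#' Alignment rotation taking one unit vector onto another
#'
#' Builds the quaternion q = (cos(theta/2), sin(theta/2) * k) with rotation
#' axis k = n x t / |n x t| and angle theta = arccos(n . t), and its
#' rotation matrix. Degenerate cases: parallel vectors give the identity;
#' antiparallel vectors rotate by pi about (1, 0, 0).
#'
#' @param n unit source vector (e.g. fitted ground normal).
#' @param t unit target vector (default +z).
#' @return object of class `alignment_transform` with `quat` and `matrix`.
#' @export
alignment_from_normal <- function(n, t = c(0, 0, 1)) {
  n <- n / sqrt(sum(n^2))
  t <- t / sqrt(sum(t^2))
  ax <- cross3(n, t)
  s <- sqrt(sum(ax^2))
  ct <- sum(n * t)
  if (s < 1e-12) {
    quat <- if (ct > 0) c(1, 0, 0, 0) else c(0, 1, 0, 0)
  } else {
    k <- ax / s
    theta <- acos(max(-1, min(1, ct)))
    quat <- c(cos(theta / 2), sin(theta / 2) * k)
  }
  structure(list(quat = quat, matrix = quat_to_matrix(quat)),
            class = "alignment_transform")
}

#' Rotate and level a scene onto the ground plane
#'
#' Applies the alignment rotation to every point (and normal), then
#' translates in z so the rotated ground plane sits at z = 0. All later
#' heights in the pipeline are plain z differences.
#'
#' @param cloud a [point_cloud].
#' @param plane the [fit_ground_plane] result the transform was built from.
#' @param transform an [alignment_from_normal] result.
#' @return the aligned [point_cloud].
#' @export
apply_alignment <- function(cloud, plane, transform) {
  R <- transform$matrix
  out <- cloud
  out$points <- cloud$points %*% t(R)
  # plane points n.p = -d map to z = -d after rotation; shift them to 0
  out$points[, 3] <- out$points[, 3] + plane$coeffs[4]
  if (!is.null(cloud$normals)) out$normals <- cloud$normals %*% t(R)
  out
}

#' Fit, align and level in one step
#'
#' Convenience wrapper: [fit_ground_plane], [alignment_from_normal]
#' (normal flipped to the +z hemisphere first), [apply_alignment].
#'
#' @inheritParams fit_ground_plane
#' @return list with `cloud` (aligned), `plane`, `transform`.
#' @export
level_scene <- function(cloud, dist_tol = 0.01, iters = 200L, seed = 1L) {
  plane <- fit_ground_plane(cloud, dist_tol, iters, seed)
  if (plane$coeffs[3] < 0) {
    plane$coeffs <- -plane$coeffs
  }
  tr <- alignment_from_normal(plane$coeffs[1:3])
  list(cloud = apply_alignment(cloud, plane, tr), plane = plane,
       transform = tr)
}

#' Statistical outlier removal
#'
#' Removes points whose mean distance to their k nearest neighbors exceeds
#' the global mean by more than `std_mult` standard deviations.
#'
#' @param cloud a [point_cloud].
#' @param k neighborhood size (k < number of points).
#' @param std_mult standard-deviation multiplier.
#' @return filtered [point_cloud] (attribute `source_indices` kept).
#' @export
remove_statistical_outliers <- function(cloud, k = 20L, std_mult = 2) {
  n <- n_points(cloud)
  if (k >= n) stop("k must be smaller than the number of points")
  nn <- RANN::nn2(cloud$points, k = k + 1L)
  md <- rowMeans(nn$nn.dists[, -1L, drop = FALSE])
  keep <- md <= mean(md) + std_mult * sd(md)
  subset_cloud(cloud, keep)
}

#' Bilateral point-cloud smoothing
#'
#' Each point is displaced along its normal by the bilaterally weighted
#' mean of its neighbors' normal offsets: spatial weight
#' exp(-|q-p|^2 / 2 sigma_s^2), range weight exp(-(n.(q-p))^2 / 2 sigma_r^2).
#' The range term preserves creases and edges. Point count is unchanged.
#'
#' @param cloud a [point_cloud]; normals are estimated if absent.
#' @param sigma_s spatial bandwidth (m).
#' @param sigma_r range bandwidth along the normal (m).
#' @param k neighborhood size.
#' @return smoothed [point_cloud].
#' @export
bilateral_smooth <- function(cloud, sigma_s = 0.01, sigma_r = 0.005, k = 20L) {
  n <- n_points(cloud)
  if (n < k + 1L) stop("need more than k points")
  if (is.null(cloud$normals)) cloud <- estimate_normals_curvature(cloud, k)
  pts <- cloud$points
  nrm <- cloud$normals
  nn <- RANN::nn2(pts, k = k + 1L)
  idx <- nn$nn.idx
  disp <- numeric(n)
  vx <- matrix(pts[idx, 1], n) - pts[, 1]
  vy <- matrix(pts[idx, 2], n) - pts[, 2]
  vz <- matrix(pts[idx, 3], n) - pts[, 3]
  dn <- vx * nrm[, 1] + vy * nrm[, 2] + vz * nrm[, 3]
  w <- exp(-(vx^2 + vy^2 + vz^2) / (2 * sigma_s^2)) *
    exp(-dn^2 / (2 * sigma_r^2))
  disp <- rowSums(w * dn) / rowSums(w)
  out <- cloud
  out$points <- pts + disp * nrm
  out
}

#' Convert RGB colors to HSI
#'
#' Standard arccos form: I = (R+G+B)/3, S = 1 - 3 min/(R+G+B), hue from
#' the arccos of the chromatic projection, reflected to (180, 360) degrees
#' when B > G. Black maps to (0, 0, 0); gray inputs give S = 0 and H = 0 by
#' convention.
#'
#' @param colors m x 3 RGB matrix in \[0, 1\].
#' @return data.frame with columns `h` (degrees in \[0, 360)), `s`, `i`.
#' @export
rgb_to_hsi <- function(colors) {
  colors <- as_xyz_matrix(colors, "colors")
  r <- colors[, 1]; g <- colors[, 2]; b <- colors[, 3]
  tot <- r + g + b
  i <- tot / 3
  mn <- pmin(r, g, b)
  s <- ifelse(tot > 0, 1 - 3 * mn / tot, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  h <- ifelse(den > 1e-12, acos(pmin(pmax(num / den, -1), 1)) * 180 / pi, 0)
  h <- ifelse(b > g, 360 - h, h)
  h[s <= 1e-12] <- 0
  h[h >= 360] <- 0
  data.frame(h = h, s = s, i = i)
}

#' Convert HSI colors to RGB
#'
#' Inverse of [rgb_to_hsi] (sector form); used mainly by the synthetic
#' field generator to paint clouds with controlled hue.
#'
#' @param h hue in degrees \[0, 360).
#' @param s saturation in \[0, 1\].
#' @param i intensity in \[0, 1\].
#' @return m x 3 RGB matrix in \[0, 1\].
#' @export
hsi_to_rgb <- function(h, s, i) {
  m <- max(length(h), length(s), length(i))
  h <- rep_len(h %% 360, m); s <- rep_len(s, m); i <- rep_len(i, m)
  r <- g <- b <- numeric(m)
  sec <- findInterval(h, c(0, 120, 240))  # 1, 2, 3
  hh <- h - c(0, 120, 240)[sec] # local hue in [0, 120)
  x <- i * (1 - s)
  y <- i * (1 + s * cos(hh * pi / 180) / cos((60 - hh) * pi / 180))
  z <- 3 * i - (x + y)
  r[sec == 1] <- y[sec == 1]; g[sec == 1] <- z[sec == 1]; b[sec == 1] <- x[sec == 1]
  r[sec == 2] <- x[sec == 2]; g[sec == 2] <- y[sec == 2]; b[sec == 2] <- z[sec == 2]
  r[sec == 3] <- z[sec == 3]; g[sec == 3] <- x[sec == 3]; b[sec == 3] <- y[sec == 3]
  pmin(pmax(cbind(r, g, b), 0), 1)
}

#' Hue-enhanced cloth simulation ground filter (HCSF)
#'
#' A virtual cloth settles onto the inverted cloud over a grid of spacing
#' `cloth_res`; points within `class_tol` of (or below) the settled cloth
#' are ground candidates. Candidates whose hue lies inside `hue_band` with
#' saturation above `sat_min` are vegetation and are vetoed back to the
#' plant side — the hue enhancement that keeps low stem collars out of the
#' ground class. The two outputs partition the cloud exactly.
#'
#' @param cloud aligned [point_cloud] (z up, ground near z = 0).
#' @param cloth_res cloth grid spacing (m).
#' @param rigidness cloth stiffness, 1-3; more is stiffer (flatter cloth).
#' @param class_tol ground classification distance (m).
#' @param hue_band numeric (lo, hi) hue degrees vetoed as vegetation.
#' @param sat_min minimum saturation for the hue veto (gray noise is not
#'   vetoed).
#' @return list with `gp` (ground plants) and `gs` (ground surface), both
#'   [point_cloud]s carrying `source_indices`.
#' @export
hcsf_split <- function(cloud, cloth_res = 0.02, rigidness = 3L,
                       class_tol = 0.015, hue_band = c(60, 180),
                       sat_min = 0.1) {
  n <- n_points(cloud)
  if (n == 0L) stop("empty cloud")
  pts <- cloud$points
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  nx <- max(1L, ceiling((xr[2] - xr[1]) / cloth_res))
  ny <- max(1L, ceiling((yr[2] - yr[1]) / cloth_res))
  ix <- pmin(pmax(floor((pts[, 1] - xr[1]) / cloth_res) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((pts[, 2] - yr[1]) / cloth_res) + 1L, 1L), ny)
  cell <- (iy - 1L) * nx + ix

  # inverted frame: z' = -z, ground becomes the upper envelope
  zi <- -pts[, 3]
  hit <- rep(NA_real_, nx * ny)
  agg <- tapply(zi, cell, max)
  hit[as.integer(names(agg))] <- agg
  hitm <- matrix(hit, nx, ny)

  cl <- hitm
  cl[is.na(cl)] <- stats::median(hit, na.rm = TRUE)
  shift_mean <- function(m) {
    up <- rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
    lf <- cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
    (up + dn + lf + rt) / 4
  }
  iters <- 25L * as.integer(rigidness)
  for (it in seq_len(iters)) {
    sm <- shift_mean(cl)
    cl <- ifelse(is.na(hitm), sm, pmax(sm, hitm))
  }

  ground_z <- -cl[cbind(ix, iy)]
  candidate <- pts[, 3] - ground_z <= class_tol
  hsi <- rgb_to_hsi(cloud$colors)
  veto <- candidate & hsi$h >= hue_band[1] & hsi$h <= hue_band[2] &
    hsi$s > sat_min
  gs_mask <- candidate & !veto
  list(gp = subset_cloud(cloud, !gs_mask), gs = subset_cloud(cloud, gs_mask))
}
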