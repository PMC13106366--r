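# Gaussian-splat scenes: each primitive is an anisotropic 3D Gaussian
# G(x) = exp(-(x-mu)' Sigma^-1 (x-mu) / 2) with Sigma = R S S' R', R the
# rotation from a unit quaternion and S = diag(s1, s2, s3). A trained scene
# file is converted to a dense colored point cloud by drawing from each
# Gaussian and rejecting draws beyond a Mahalanobis radius.

# band-0 spherical harmonic constant 1/(2*sqrt(pi)) used by splat exporters
SH_C0 <- 0.2820947918

#' Construct a splat set
#'
#' @param mu n x 3 matrix of Gaussian centers (m).
#' @param scale n x 3 matrix of per-axis standard deviations (m), > 0.
#' @param rot n x 4 matrix of unit quaternions (w, x, y, z).
#' @param opacity numeric vector in \[0, 1\].
#' @param color n x 3 RGB matrix in \[0, 1\].
#' @return object of class `splat_set`.
#' @export
splat_set <- function(mu, scale, rot, opacity, color) {
  mu <- as_xyz_matrix(mu, "mu")
  scale <- as_xyz_matrix(scale, "scale")
  color <- as_xyz_matrix(color, "color")
  rot <- as.matrix(rot)
  storage.mode(rot) <- "double"
  if (ncol(rot) != 4L) stop("rot must have 4 columns (w, x, y, z)")
  if (any(!is.finite(mu)) || any(!is.finite(scale)) || any(!is.finite(rot)))
    stop("non-finite splat parameters")
  if (any(scale <= 0)) stop("scales must be positive")
  qn <- sqrt(rowSums(rot^2))
  if (any(abs(qn - 1) > 1e-6)) stop("quaternions must be unit norm")
  structure(list(mu = mu, scale = scale, rot = rot / qn,
                 opacity = pmin(pmax(as.numeric(opacity), 0), 1),
                 color = pmin(pmax(color, 0), 1)),
            class = "splat_set")
}

#' @export
print.splat_set <- function(x, ...) {
  cat("splat_set:", nrow(x$mu), "Gaussian primitives\n")
  invisible(x)
}

n_splats <- function(s) nrow(s$mu)

#' Load a Gaussian-splat scene file
#'
#' Reads the community PLY dialect written by splat trainers: per-vertex
#' `x,y,z`, `scale_0..2` (log of the axis standard deviations),
#' `rot_0..3` (quaternion, w first), `opacity` (logit), and `f_dc_0..2`
#' (band-0 spherical-harmonic color coefficients). Scales are
#' exponentiated, opacity passed through the logistic, quaternions
#' normalized, and DC coefficients mapped to RGB as
#' `clamp(0.5 + C0 * f_dc)` with `C0 = 1/(2*sqrt(pi))`.
#'
#' @param path PLY scene file.
#' @return a [splat_set].
#' @export
load_splats <- function(path) {
  v <- read_ply_vertices(path)
  need <- c("x", "y", "z", paste0("scale_", 0:2), paste0("rot_", 0:3),
            "opacity", paste0("f_dc_", 0:2))
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("splat PLY lacks fields: ", paste(miss, collapse = ", "))
  if (any(!sapply(v[need], function(col) all(is.finite(col)))))
    stop("non-finite values in splat file")
  splat_set(
    mu = cbind(v$x, v$y, v$z),
    scale = exp(cbind(v$scale_0, v$scale_1, v$scale_2)),
    rot = {
      q <- cbind(v$rot_0, v$rot_1, v$rot_2, v$rot_3)
      q / sqrt(rowSums(q^2))
    },
    opacity = stats::plogis(v$opacity),
    color = pmin(pmax(0.5 + SH_C0 * cbind(v$f_dc_0, v$f_dc_1, v$f_dc_2), 0), 1)
  )
}

#' Sample a dense point cloud from a splat set
#'
#' Draws from each Gaussian primitive in proportion to
#' `opacity * (s1*s2*s3)^(1/3)` (opacity-weighted size), scaled so the
#' total number of draws is about `budget`. Each draw `x = mu + R S z`
#' with `z ~ N(0, I)` is kept only if its Mahalanobis distance
#' `sqrt(z'z)` is at most `mahal_max`; Sigma is never inverted directly,
#' the rejection works in the factorized frame. Primitives with opacity
#' below `min_opacity` are skipped (floater suppression). Fixed `seed`
#' gives identical clouds.
#'
#' @param splats a [splat_set].
#' @param budget approximate total number of draws (before rejection).
#' @param mahal_max Mahalanobis rejection radius (default 3: keeps ~97% of
#'   the mass of each Gaussian).
#' @param seed integer RNG seed.
#' @param min_opacity primitives below this opacity contribute no points.
#' @return a [point_cloud]; attribute `splat_index` maps each point to its
#'   source primitive.
#' @export
sample_points <- function(splats, budget = 1e5, mahal_max = 3, seed = 1L,
                          min_opacity = 0.05) {
  if (!inherits(splats, "splat_set")) stop("splats must be a splat_set")
  n <- n_splats(splats)
  if (n == 0L) stop("empty splat set")
  if (mahal_max <= 0) stop("mahal_max must be > 0")
  if (any(splats$scale < 1e-12)) stop("singular covariance: scale underflow")
  w <- splats$opacity * apply(splats$scale, 1, function(s) prod(s)^(1 / 3))
  w[splats$opacity < min_opacity] <- 0
  if (sum(w) == 0) stop("no primitive passes the opacity floor")
  draws <- round(budget * w / sum(w))
  set.seed(seed)
  pts <- vector("list", n)
  src <- vector("list", n)
  for (i in seq_len(n)) {
    m <- draws[i]
    if (m == 0L) next
    z <- matrix(rnorm(3 * m), m, 3)
    keep <- rowSums(z^2) <= mahal_max^2
    if (!any(keep)) next
    z <- z[keep, , drop = FALSE]
    R <- quat_to_matrix(splats$rot[i, ])
    x <- z %*% (t(R) * splats$scale[i, ])  # (R diag(s) z)' = z' diag(s) R'
    pts[[i]] <- sweep(x, 2, splats$mu[i, ], "+")
    src[[i]] <- rep.int(i, nrow(z))
  }
  keep_i <- !vapply(pts, is.null, logical(1))
  if (!any(keep_i)) stop("all draws rejected; increase budget or mahal_max")
  src <- unlist(src[keep_i])
  out <- point_cloud(do.call(rbind, pts[keep_i]),
                     splats$color[src, , drop = FALSE])
  attr(out, "splat_index") <- src
  out
}

#' Mahalanobis distance of points to one splat primitive
#'
#' Computed through the R, S factorization of the covariance
#' (`z = S^-1 R' (x - mu)`, distance `sqrt(z'z)`), never by generic matrix
#' inversion.
#'
#' @param splats a [splat_set].
#' @param i primitive index.
#' @param pts m x 3 matrix of query points.
#' @return numeric vector of Mahalanobis distances.
#' @export
mahalanobis_to_splat <- function(splats, i, pts) {
  R <- quat_to_matrix(splats$rot[i, ])
  d <- sweep(as_xyz_matrix(pts, "pts"), 2, splats$mu[i, ], "-")
  z <- sweep(d %*% R, 2, splats$scale[i, ], "/")
  sqrt(rowSums(z^2))
}

#' Covariance matrix of one splat primitive
#'
#' `Sigma = R S S' R'` from the stored quaternion and axis scales.
#'
#' @inheritParams mahalanobis_to_splat
#' @return 3 x 3 covariance matrix.
#' @export
splat_covariance <- function(splats, i) {
  R <- quat_to_matrix(splats$rot[i, ])
  S <- diag(splats$scale[i, ]^2)
  R %*% S %*% t(R)
}
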