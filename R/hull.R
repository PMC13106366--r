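# Incremental 3D convex hull (no external geometry library in this stack).
# Faces are maintained outward-oriented; each remaining point either lies
# inside the current hull or removes its visible faces and is stitched to
# the horizon. Exactness is to a tolerance scaled by the cloud diameter.

#' Convex hull of a 3D point set
#'
#' @param pts m x 3 coordinate matrix with at least 4 non-coplanar points.
#' @return list with `faces` (t x 3 vertex indices, outward orientation),
#'   `vertices` (indices of hull vertices), `area` (surface area) and
#'   `volume`, in the squared / cubed units of `pts`.
#' @export
convex_hull_3d <- function(pts) {
  pts <- as_xyz_matrix(pts, "pts")
  n <- nrow(pts)
  if (n < 4L) stop("degenerate hull: need at least 4 points")
  diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  if (diam == 0) stop("degenerate hull: all points identical")
  eps <- 1e-9 * diam

  # initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  v <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  tproj <- (w %*% v) / sum(v^2)
  d2 <- rowSums((w - tproj %*% t(v))^2)
  i3 <- which.max(d2)
  if (sqrt(d2[i3]) < eps) stop("degenerate hull: points are collinear")
  nrm0 <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm0 <- nrm0 / sqrt(sum(nrm0^2))
  d3 <- abs(w %*% nrm0)
  i4 <- which.max(d3)
  if (d3[i4] < eps) stop("degenerate hull: points are coplanar")

  ctr <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nr <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nr * (ctr - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- rbind(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                 orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))

  face_geo <- function(faces) {
    a <- pts[faces[, 1], , drop = FALSE]
    nr <- t(apply(faces, 1, function(f)
      cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])))
    list(normals = nr, base = a)
  }

  todo <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  geo <- face_geo(faces)
  for (p in todo) {
    vis <- rowSums(geo$normals * (rep(1, nrow(faces)) %o% pts[p, ] - geo$base)) > eps
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    # directed edges of visible faces; horizon = edges whose reverse is
    # not itself a visible-face edge
    ed <- rbind(visf[, 1:2], visf[, 2:3], visf[, c(3, 1)])
    keys <- paste(ed[, 1], ed[, 2])
    rkeys <- paste(ed[, 2], ed[, 1])
    horizon <- ed[!(rkeys %in% keys), , drop = FALSE]
    newf <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
    geo <- face_geo(faces)
  }

  nr <- geo$normals
  lens <- sqrt(rowSums(nr^2))
  area <- sum(lens) / 2
  vol <- abs(sum(vapply(seq_len(nrow(faces)), function(i) {
    f <- faces[i, ]
    sum(pts[f[1], ] * cross3(pts[f[2], ], pts[f[3], ]))
  }, numeric(1)))) / 6
  list(faces = faces, vertices = sort(unique(as.vector(faces))),
       area = area, volume = vol)
}
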