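# Seeded generator of synthetic seedling-stage cotton fields with exact
# ground truth. Morphology is deliberately simple — a gently bowed stem
# cylinder, petiole cylinders, bent elliptical laminae — but rich enough to
# exercise every pipeline stage: bare stems for the localization layer,
# planar laminae for plane fits, curvature contrast between tubes and
# blades, hue contrast between ground and canopy, and a leaf span that
# grows with `overlap_factor` to force contested points between neighbors.
# All leaf areas are analytic (quadrature over the generating patch), never
# measured from the sampled points.

#' Synthetic field specification
#'
#' Defaults emulate a 2 m x 2 m precision-seeded plot at the 6-7 leaf
#' stage: 0.66 m row spacing, 0.10 m plant spacing, near-planar ground of
#' distinct (brown) hue, green canopy, additive isotropic sensor noise.
#'
#' @param rows,cols plant grid size (rows along y, plants per row along x).
#' @param row_spacing,plant_spacing grid spacings (m).
#' @param spacing_jitter uniform jitter of each stem base (m).
#' @param plot_size ground extent (m, square).
#' @param ground_hue,plant_hue HSI hue (degrees) of ground and canopy.
#' @param noise_sigma isotropic additive noise standard deviation (m).
#' @param points_per_plant sampled points per plant.
#' @param ground_points sampled ground points.
#' @param overlap_factor >= 0; stretches petioles and laminae toward the
#'   neighbors (0 = fully separated plants, ~1.5 = heavy interpenetration).
#' @param seed integer RNG seed; full determinism.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(rows = 3L, cols = 3L, row_spacing = 0.66,
                       plant_spacing = 0.10, spacing_jitter = 0.008,
                       plot_size = 2.0, ground_hue = 30, plant_hue = 110,
                       noise_sigma = 0.003, points_per_plant = 3000L,
                       ground_points = 24000L, overlap_factor = 0.5,
                       seed = 1L) {
  stopifnot(row_spacing > 0, plant_spacing > 0, noise_sigma >= 0,
            overlap_factor >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 row_spacing = row_spacing, plant_spacing = plant_spacing,
                 spacing_jitter = spacing_jitter, plot_size = plot_size,
                 ground_hue = ground_hue, plant_hue = plant_hue,
                 noise_sigma = noise_sigma,
                 points_per_plant = as.integer(points_per_plant),
                 ground_points = as.integer(ground_points),
                 overlap_factor = overlap_factor, seed = as.integer(seed)),
            class = "field_spec")
}

# exact-total proportional allocation
alloc_counts <- function(w, total) {
  cs <- round(cumsum(w) * total / sum(w))
  diff(c(0L, cs))
}

# analytic area of the bent elliptical lamina
# r(u, v) = u e1 + v e2 + (bend/a) u^2 e3, (u/a)^2 + (v/b)^2 <= 1
# |r_u x r_v| = sqrt(1 + (2 bend u / a)^2)
lamina_area <- function(a, b, bend, n_grid = 2000L) {
  u <- (seq_len(n_grid) - 0.5) / n_grid * 2 * a - a
  du <- 2 * a / n_grid
  sum(sqrt(1 + (2 * bend * u / a)^2) * 2 * b * sqrt(pmax(1 - (u / a)^2, 0))) * du
}

# sample m points on the lamina, uniform by surface area
sample_lamina <- function(m, a, b, bend) {
  ng <- 512L
  u_grid <- (seq_len(ng) - 0.5) / ng * 2 * a - a
  wts <- sqrt(1 + (2 * bend * u_grid / a)^2) * sqrt(pmax(1 - (u_grid / a)^2, 0))
  bin <- sample.int(ng, m, replace = TRUE, prob = wts)
  u <- u_grid[bin] + (runif(m) - 0.5) * (2 * a / ng)
  u <- pmin(pmax(u, -a), a)
  half <- b * sqrt(pmax(1 - (u / a)^2, 0))
  v <- runif(m, -half, half)
  cbind(u, v, bend * u^2 / a)
}

# sample m points on a cylinder wall from `base` along unit `dir`
sample_tube <- function(m, base, dir, len, radius) {
  t <- runif(m, 0, len)
  phi <- runif(m, 0, 2 * pi)
  # orthonormal frame around dir
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(dir, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(dir, e1)
  sweep(outer(t, dir) + radius * (outer(cos(phi), e1) + outer(sin(phi), e2)),
        2, base, "+")
}

#' Generate one synthetic plant
#'
#' Stem: a noiseless cylinder around a gently bowed vertical polyline.
#' The first two leaves are the cotyledon pair, inserted at `cotyledon_z`
#' on opposite sides; further leaves sit at nodes spaced up the stem with
#' golden-angle azimuths. Each leaf is a petiole tube plus a bent
#' elliptical lamina; points are sampled uniformly by surface area and the
#' lamina areas are computed analytically by quadrature. Isotropic
#' N(0, noise_sigma^2) noise is added last (same seed and structure, only
#' the noise scale changes with `noise_sigma`).
#'
#' Uses the ambient RNG stream: seed it (or call from [generate_field])
#' for reproducibility.
#'
#' @param stem_base numeric (x, y) of the stem base; z = 0.
#' @param height stem height (m), in \[0.15, 0.6\].
#' @param cotyledon_z cotyledon node height (m).
#' @param leaf_count total laminae including the cotyledon pair, 2-8.
#' @param overlap_factor leaf-span stretch, as in [field_spec].
#' @param noise_sigma additive noise sd (m).
#' @param n_points points to sample on the plant.
#' @param plant_hue canopy hue (degrees).
#' @param quad_grid quadrature resolution for the analytic leaf areas.
#' @return list with `points`, `colors`, `parts` (factor: stem / petiole /
#'   leaf), `leaf_id` (0 for non-lamina points) and `truth` (stem_base,
#'   height, cotyledon_z, leaf_count, leaf_areas).
#' @export
generate_plant <- function(stem_base = c(0, 0), height = 0.30,
                           cotyledon_z = 0.07, leaf_count = 4L,
                           overlap_factor = 0.5, noise_sigma = 0,
                           n_points = 3000L, plant_hue = 110,
                           quad_grid = 2000L) {
  if (height < 0.15 || height > 0.6) stop("height out of range [0.15, 0.6]")
  if (leaf_count < 2L || leaf_count > 8L) stop("leaf_count out of range [2, 8]")
  if (cotyledon_z <= 0 || cotyledon_z >= height) stop("invalid cotyledon_z")
  stem_r <- 0.004
  pet_r <- 0.0015
  pet_len <- 0.012 + 0.010 * overlap_factor
  lam_a <- 0.012 + 0.016 * overlap_factor
  lam_b <- 0.7 * lam_a
  bow <- runif(1, 0, 0.008)
  bow_az <- runif(1, 0, 2 * pi)
  theta0 <- runif(1, 0, 2 * pi)

  axis_at <- function(z) {
    s <- bow * (z / height)^2
    c(stem_base[1] + s * cos(bow_az), stem_base[2] + s * sin(bow_az), z)
  }

  # leaf placements: 2 cotyledons then nodes up the stem
  n_leaves <- leaf_count
  leaf_z <- c(cotyledon_z, cotyledon_z,
              if (n_leaves > 2L)
                seq(cotyledon_z + 0.04, 0.85 * height,
                    length.out = n_leaves - 2L))
  leaf_az <- c(theta0, theta0 + pi,
               if (n_leaves > 2L)
                 theta0 + pi / 2 + (seq_len(n_leaves - 2L)) * 137.5 * pi / 180)
  leaf_elev <- runif(n_leaves, 20, 40) * pi / 180
  leaf_elev[1:2] <- runif(2, 10, 20) * pi / 180
  leaf_scale <- c(0.8, 0.8, rep(1, n_leaves - 2L))
  leaf_bend <- runif(n_leaves, 0.08, 0.2)

  a_k <- lam_a * leaf_scale
  b_k <- lam_b * leaf_scale
  areas <- vapply(seq_len(n_leaves), function(k)
    lamina_area(a_k[k], b_k[k], leaf_bend[k] * a_k[k], quad_grid), numeric(1))

  stem_area <- 2 * pi * stem_r * height
  pet_area <- 2 * pi * pet_r * pet_len * leaf_scale
  counts <- alloc_counts(c(stem_area, pet_area, areas), n_points)
  n_stem <- counts[1]
  n_pet <- counts[1 + seq_len(n_leaves)]
  n_lam <- counts[1 + n_leaves + seq_len(n_leaves)]

  # stem points
  zs <- runif(n_stem, 0, height)
  phis <- runif(n_stem, 0, 2 * pi)
  ax <- t(vapply(zs, axis_at, numeric(3)))
  stem_pts <- ax + cbind(stem_r * cos(phis), stem_r * sin(phis), 0)

  pts <- list(stem_pts)
  parts <- list(rep("stem", n_stem))
  leaf_id <- list(rep(0L, n_stem))
  for (k in seq_len(n_leaves)) {
    anchor <- axis_at(leaf_z[k])
    dir <- c(cos(leaf_az[k]) * cos(leaf_elev[k]),
             sin(leaf_az[k]) * cos(leaf_elev[k]),
             sin(leaf_elev[k]))
    plen <- pet_len * leaf_scale[k]
    if (n_pet[k] > 0) {
      pts[[length(pts) + 1L]] <- sample_tube(n_pet[k], anchor, dir, plen, pet_r)
      parts[[length(parts) + 1L]] <- rep("petiole", n_pet[k])
      leaf_id[[length(leaf_id) + 1L]] <- rep(0L, n_pet[k])
    }
    # lamina frame: e1 tilted slightly up from the petiole, e2 horizontal
    tip <- anchor + plen * dir
    e1 <- dir
    e2 <- c(-sin(leaf_az[k]), cos(leaf_az[k]), 0)
    e3 <- cross3(e1, e2)
    if (n_lam[k] > 0) {
      uvw <- sample_lamina(n_lam[k], a_k[k], b_k[k], leaf_bend[k] * a_k[k])
      ctrv <- tip + a_k[k] * e1
      pts[[length(pts) + 1L]] <-
        sweep(uvw %*% rbind(e1, e2, e3), 2, ctrv, "+")
      parts[[length(parts) + 1L]] <- rep("leaf", n_lam[k])
      leaf_id[[length(leaf_id) + 1L]] <- rep(as.integer(k), n_lam[k])
    }
  }

  points <- do.call(rbind, pts)
  parts <- factor(unlist(parts), levels = c("stem", "petiole", "leaf"))
  leaf_id <- unlist(leaf_id)
  m <- nrow(points)
  hsv_h <- plant_hue + runif(m, -10, 10)
  colors <- hsi_to_rgb(hsv_h, runif(m, 0.45, 0.7), runif(m, 0.25, 0.45))
  noise <- matrix(rnorm(3 * m), m, 3) * noise_sigma
  list(points = points + noise, colors = colors, parts = parts,
       leaf_id = leaf_id,
       truth = list(stem_base = c(stem_base[1], stem_base[2], 0),
                    height = height, cotyledon_z = cotyledon_z,
                    leaf_count = n_leaves, leaf_areas = areas))
}

#' Generate a synthetic field with ground-truth labels
#'
#' Plants at jittered grid positions on a near-planar ground of distinct
#' hue (smooth undulation plus the same additive sensor noise). Labels:
#' 0 = ground, k = plant k, numbered row-major by (y, x). Stem bases whose
#' jitter would collide (< 0.04 m apart) are resampled with a warning.
#'
#' @param spec a [field_spec].
#' @return list with `cloud` (labeled [point_cloud]), `truths` (list of
#'   per-plant truth lists, entry k for plant k).
#' @export
generate_field <- function(spec = field_spec()) {
  set.seed(spec$seed)
  g <- expand.grid(
    x = (seq_len(spec$cols) - (spec$cols + 1) / 2) * spec$plant_spacing,
    y = (seq_len(spec$rows) - (spec$rows + 1) / 2) * spec$row_spacing
  )
  half <- spec$plot_size / 2
  if (any(abs(g$x) > half - 0.1) || any(abs(g$y) > half - 0.1))
    stop("grid does not fit the plot")
  for (try in 1:20) {
    bx <- g$x + runif(nrow(g), -spec$spacing_jitter, spec$spacing_jitter)
    by <- g$y + runif(nrow(g), -spec$spacing_jitter, spec$spacing_jitter)
    dmin <- if (nrow(g) > 1L) min(dist(cbind(bx, by))) else Inf
    if (dmin >= 0.04) break
    warning("stem bases collide; resampling jitter")
  }
  ord <- order(by, bx)
  bx <- bx[ord]; by <- by[ord]
  K <- nrow(g)

  # per-plant morphology
  heights <- runif(K, 0.25, 0.35)
  cotyl <- runif(K, 0.065, 0.09)
  nleaf <- sample(4:6, K, replace = TRUE)

  plant_out <- vector("list", K)
  for (k in seq_len(K)) {
    plant_out[[k]] <- generate_plant(
      stem_base = c(bx[k], by[k]), height = heights[k],
      cotyledon_z = cotyl[k], leaf_count = nleaf[k],
      overlap_factor = spec$overlap_factor, noise_sigma = 0,
      n_points = spec$points_per_plant, plant_hue = spec$plant_hue
    )
  }

  # ground: uniform xy, smooth undulation
  ng <- spec$ground_points
  gx <- runif(ng, -half, half)
  gy <- runif(ng, -half, half)
  ph1 <- runif(2, 0, 2 * pi)
  gz <- 0.003 * sin(2 * pi * gx / 0.9 + ph1[1]) * sin(2 * pi * gy / 1.1 + ph1[2])
  gcol <- hsi_to_rgb(spec$ground_hue + runif(ng, -8, 8),
                     runif(ng, 0.25, 0.45), runif(ng, 0.3, 0.5))

  pts <- rbind(cbind(gx, gy, gz),
               do.call(rbind, lapply(plant_out, `[[`, "points")))
  cols <- rbind(gcol, do.call(rbind, lapply(plant_out, `[[`, "colors")))
  labels <- c(rep(0L, ng),
              unlist(lapply(seq_len(K), function(k)
                rep(k, nrow(plant_out[[k]]$points)))))

  # noise last: changing only noise_sigma rescales the same draws, so
  # labels and the truth table are invariant to it
  noise <- matrix(rnorm(3 * nrow(pts)), ncol = 3) * spec$noise_sigma
  cloud <- point_cloud(pts + noise, cols, labels = labels)

  truths <- lapply(seq_len(K), function(k) {
    tr <- plant_out[[k]]$truth
    tr$plant_index <- k
    tr$point_indices <- which(labels == k)
    tr$parts <- plant_out[[k]]$parts
    tr$leaf_id <- plant_out[[k]]$leaf_id
    tr
  })
  list(cloud = cloud, truths = truths, spec = spec)
}

#' Ground-truth trait table
#'
#' Analytic traits straight from the generator parameters (FCNH =
#' cotyledon insertion height, PH = stem height, leaf areas from the patch
#' quadrature), for direct comparison with measured [extract_traits]
#' output.
#'
#' @param truths `truths` list from [generate_field].
#' @return data.frame with `plant_index`, `fcnh`, `ph`, `leaf_count`,
#'   `la_total`.
#' @export
truth_traits <- function(truths) {
  data.frame(
    plant_index = vapply(truths, `[[`, numeric(1), "plant_index"),
    fcnh = vapply(truths, `[[`, numeric(1), "cotyledon_z"),
    ph = vapply(truths, `[[`, numeric(1), "height"),
    leaf_count = vapply(truths, function(t) as.numeric(t$leaf_count),
                        numeric(1)),
    la_total = vapply(truths, function(t) sum(t$leaf_areas), numeric(1))
  )
}
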