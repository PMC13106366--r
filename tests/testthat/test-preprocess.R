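test_that("RANSAC recovers an exact ground plane under clutter", {
  set.seed(21)
  ground <- cbind(runif(1000), runif(1000), 0)
  clutter <- cbind(runif(100), runif(100), runif(100, 0.1, 0.3))
  pl <- fit_ground_plane(point_cloud(rbind(ground, clutter)),
                         dist_tol = 0.005, seed = 3)
  expect_lt(max(abs(pl$coeffs - c(0, 0, 1, 0))), 1e-6)
  expect_true(all(pl$inlier_indices <= 1000))
  expect_equal(length(pl$inlier_indices), 1000L)
})

test_that("plane offset carries the right sign convention", {
  set.seed(22)
  pts <- cbind(runif(200), runif(200), 0.02)
  pl <- fit_ground_plane(point_cloud(pts), dist_tol = 0.005, seed = 1)
  expect_equal(pl$coeffs[1:3], c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$coeffs[4], -0.02, tolerance = 1e-9)
})

test_that("plane fitting needs 3 non-collinear points", {
  expect_error(fit_ground_plane(point_cloud(matrix(runif(6), 2))), "3 points")
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(fit_ground_plane(point_cloud(line), seed = 1), "degenerate")
})

test_that("alignment rotation maps n onto t with the stated quaternion", {
  id <- alignment_from_normal(c(0, 0, 1))
  expect_equal(id$matrix, diag(3), tolerance = 1e-12)
  expect_equal(id$quat, c(1, 0, 0, 0))

  tr <- alignment_from_normal(c(1, 0, 0))
  # oracle: direct expansion of the quaternion-to-matrix formula for a
  # rotation of pi/2 about the axis (1,0,0) x (0,0,1) / |.| = (0,-1,0)
  qt <- c(cos(pi / 4), sin(pi / 4) * c(0, -1, 0))
  R_expected <- rbind(
    c(1 - 2 * qt[3]^2 - 2 * qt[4]^2,
      2 * qt[2] * qt[3] - 2 * qt[4] * qt[1],
      2 * qt[2] * qt[4] + 2 * qt[3] * qt[1]),
    c(2 * qt[2] * qt[3] + 2 * qt[4] * qt[1],
      1 - 2 * qt[2]^2 - 2 * qt[4]^2,
      2 * qt[3] * qt[4] - 2 * qt[2] * qt[1]),
    c(2 * qt[2] * qt[4] - 2 * qt[3] * qt[1],
      2 * qt[3] * qt[4] + 2 * qt[2] * qt[1],
      1 - 2 * qt[2]^2 - 2 * qt[3]^2))
  expect_equal(tr$matrix, R_expected, tolerance = 1e-12)
  expect_lt(max(abs(tr$matrix %*% c(1, 0, 0) - c(0, 0, 1))), 1e-12)

  anti <- alignment_from_normal(c(0, 0, -1))
  expect_equal(anti$quat, c(0, 1, 0, 0))
  expect_equal(as.vector(anti$matrix %*% c(0, 0, -1)), c(0, 0, 1),
               tolerance = 1e-12)
})

test_that("alignment property holds over 1000 random normals", {
  set.seed(23)
  worst_map <- 0
  worst_orth <- 0
  for (i in 1:1000) {
    n <- rnorm(3)
    n <- n / sqrt(sum(n^2))
    tr <- alignment_from_normal(n)
    worst_map <- max(worst_map, sqrt(sum((tr$matrix %*% n - c(0, 0, 1))^2)))
    worst_orth <- max(worst_orth,
                      max(abs(crossprod(tr$matrix) - diag(3))))
  }
  expect_lt(worst_map, 1e-9)
  expect_lt(worst_orth, 1e-9)
})

test_that("apply_alignment levels a tilted scene and is a rigid motion", {
  set.seed(24)
  n0 <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  u <- cbind(runif(800, -1, 1), runif(800, -1, 1))
  basis <- cbind(c(n0[3], 0, -n0[1]), c(0, 1, 0))
  ground <- u %*% t(basis) + 0.05  # tilted plane, offset from origin
  tops <- ground[1:50, ] + rep(n0, each = 50) * 0.2
  pc <- point_cloud(rbind(ground, tops))
  lv <- level_scene(pc, dist_tol = 0.005, seed = 2)
  expect_lt(max(abs(lv$cloud$points[1:800, 3])), 0.005)
  d_before <- dist(pc$points[1:20, ])
  d_after <- dist(lv$cloud$points[1:20, ])
  expect_lt(max(abs(d_before - d_after)), 1e-9)

  # already-aligned scene: rotation is numerically the identity
  lv2 <- level_scene(lv$cloud, dist_tol = 0.005, seed = 2)
  expect_lt(max(abs(lv2$cloud$points - lv$cloud$points)), 1e-6)
})

test_that("SOR removes exactly a planted far outlier", {
  set.seed(25)
  blob <- matrix(rnorm(3000, sd = 0.02), 1000)
  far <- c(1, 0, 0)
  pc <- point_cloud(rbind(blob, far))
  out <- remove_statistical_outliers(pc, k = 10, std_mult = 2)
  expect_equal(n_points(out), 1000L)
  expect_equal(attr(out, "source_indices"), 1:1000)
  expect_error(remove_statistical_outliers(random_cloud(5), k = 10), "k must")
})

test_that("SOR matches the brute-force filter and is near-idempotent", {
  set.seed(26)
  pc <- random_cloud(200)
  keep <- brute_sor(pc$points, 10, 2)
  out <- remove_statistical_outliers(pc, k = 10, std_mult = 2)
  expect_equal(attr(out, "source_indices"), keep)

  # a uniform box loses only a small edge fraction, and a second pass
  # removes less than the first (near-idempotence)
  box <- point_cloud(matrix(runif(3 * 2000), ncol = 3))
  g <- remove_statistical_outliers(box, k = 20, std_mult = 2)
  expect_gte(n_points(g) / 2000, 0.95)
  twice <- remove_statistical_outliers(g, k = 20, std_mult = 2)
  expect_lt(n_points(g) - n_points(twice), n_points(box) - n_points(g))
  expect_lte((n_points(g) - n_points(twice)) / n_points(g), 0.05)
})

test_that("bilateral smoothing shrinks plane noise and respects clean data", {
  set.seed(27)
  base <- cbind(runif(3000), runif(3000), 0)
  noisy <- base + cbind(0, 0, rnorm(3000, sd = 0.002))
  sm <- bilateral_smooth(point_cloud(noisy), k = 20)
  expect_equal(n_points(sm), 3000L)
  rms <- function(m) sqrt(mean(m[, 3]^2))
  expect_lt(rms(sm$points), 0.7 * rms(noisy))

  clean <- bilateral_smooth(point_cloud(base), k = 20)
  expect_lt(max(abs(clean$points - base)), 1e-6)
})

test_that("bilateral smoothing preserves a right-angle crease", {
  set.seed(28)
  a <- cbind(runif(2000), runif(2000), 0)
  b <- cbind(runif(2000), 0, runif(2000))
  pc <- point_cloud(rbind(a, b))
  sm <- bilateral_smooth(pc, sigma_s = 0.01, sigma_r = 0.005, k = 20)
  crease <- which(pc$points[, 2] < 0.01 & pc$points[, 3] < 0.01)
  disp <- sqrt(rowSums((sm$points[crease, ] - pc$points[crease, ])^2))
  expect_lte(max(disp), 0.005 + 1e-9)
})

test_that("RGB to HSI hits the canonical colors", {
  hsi <- rgb_to_hsi(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                          c(0.5, 0.5, 0.5), c(0, 0, 0)))
  expect_equal(hsi$h, c(0, 120, 240, 0, 0), tolerance = 1e-9)
  expect_equal(hsi$s, c(1, 1, 1, 0, 0), tolerance = 1e-9)
  expect_equal(hsi$i, c(1 / 3, 1 / 3, 1 / 3, 0.5, 0), tolerance = 1e-9)
})

test_that("HSI conversion roundtrips through its inverse", {
  set.seed(29)
  # stay inside the RGB gamut: i (1 + 2 s) <= 1
  h <- runif(200, 0, 359)
  s <- runif(200, 0.05, 0.9)
  i <- runif(200, 0.05, 0.33)
  back <- rgb_to_hsi(hsi_to_rgb(h, s, i))
  expect_lt(max(abs(back$i - i)), 1e-9)
  expect_lt(max(abs(back$s - s)), 1e-6)
  dh <- pmin(abs(back$h - h), 360 - abs(back$h - h))
  expect_lt(max(dh), 1e-3)
})

test_that("HCSF classifies a bare plane entirely as ground", {
  set.seed(30)
  pts <- cbind(runif(4000, -0.5, 0.5), runif(4000, -0.5, 0.5), 0)
  cols <- hsi_to_rgb(30, 0.3, 0.4)[rep(1, 4000), ]
  sp <- hcsf_split(point_cloud(pts, cols))
  expect_equal(n_points(sp$gp), 0L)
  expect_equal(n_points(sp$gs), 4000L)
})

test_that("HCSF keeps an elevated green point in the plant side", {
  set.seed(31)
  ground <- cbind(runif(4000, -0.5, 0.5), runif(4000, -0.5, 0.5), 0)
  pts <- rbind(ground, c(0, 0, 0.5))
  cols <- rbind(hsi_to_rgb(30, 0.3, 0.4)[rep(1, 4000), ],
                hsi_to_rgb(110, 0.6, 0.35))
  sp <- hcsf_split(point_cloud(pts, cols))
  expect_true(4001L %in% attr(sp$gp, "source_indices"))
})

test_that("HCSF separates a synthetic field and partitions exactly", {
  fld <- generate_field(field_spec(seed = 41))
  sp <- hcsf_split(fld$cloud)
  gt <- fld$cloud$labels
  gs_gt <- gt[attr(sp$gs, "source_indices")]
  gp_gt <- gt[attr(sp$gp, "source_indices")]
  expect_gte(sum(gs_gt == 0) / sum(gt == 0), 0.98)  # ground recovered
  expect_gte(sum(gp_gt > 0) / sum(gt > 0), 0.98)    # plants recovered
  expect_equal(n_points(sp$gp) + n_points(sp$gs), n_points(fld$cloud))
  expect_length(intersect(attr(sp$gp, "source_indices"),
                          attr(sp$gs, "source_indices")), 0)
})
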