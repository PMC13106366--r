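test_that("ground datum is a local median and tracks slope", {
  set.seed(81)
  flat <- point_cloud(cbind(runif(3000, -0.5, 0.5), runif(3000, -0.5, 0.5),
                            rnorm(3000, sd = 0.002)))
  gd <- ground_datum(flat, c(0, 0, 0.06))
  expect_lt(abs(gd$z_gd), 0.002)
  expect_equal(gd$flag, "")

  x <- runif(4000, -1, 1)
  slope <- point_cloud(cbind(x, runif(4000, -1, 1),
                             0.02 * x + rnorm(4000, sd = 0.002)))
  g1 <- ground_datum(slope, c(-0.8, 0, 0))$z_gd
  g2 <- ground_datum(slope, c(0.8, 0, 0))$z_gd
  expect_lt(abs(g1 - (-0.016)), 0.005)
  expect_lt(abs(g2 - 0.016), 0.005)

  expect_warning(gd3 <- ground_datum(flat, c(50, 50, 0)), "global")
  expect_equal(gd3$flag, "global_datum")
})

test_that("plant height subtracts the datum and is translation-invariant", {
  pc <- point_cloud(cbind(0, 0, c(0.1, 0.35)))
  expect_equal(plant_height(pc, 0.01), 0.34)
  shifted <- point_cloud(pc$points + rep(c(0, 0, 0.1), each = 2))
  expect_equal(plant_height(shifted, 0.11), 0.34)
  expect_error(plant_height(subset_cloud(pc, integer(0)), 0), "empty")
})

test_that("plant height recovers generator truth within 2% under noise", {
  set.seed(82)
  ok <- 0
  for (i in 1:20) {
    h <- runif(1, 0.25, 0.35)
    pl <- generate_plant(c(0, 0), h, runif(1, 0.065, 0.09), 4,
                         noise_sigma = 0.003, n_points = 1500)
    ph <- max(bilateral_smooth(point_cloud(pl$points), k = 20)$points[, 3])
    ok <- ok + (abs(ph - h) / h <= 0.02)
  }
  expect_gte(ok / 20, 0.95)
})

test_that("cotyledon node detection hits the generator insertion height", {
  set.seed(83)
  pl <- generate_plant(c(0, 0), 0.30, 0.070, 5, noise_sigma = 0,
                       n_points = 3000)
  nd <- detect_cotyledon_node(point_cloud(pl$points))
  expect_equal(nd$confidence, "ok")
  expect_lte(abs(nd$z_fn - 0.070), 0.005)
})

test_that("the minimum-z rule picks the lowest of several branch levels", {
  set.seed(84)
  # bare stem with three horizontal branch pairs at 0.06, 0.12, 0.18
  stem <- cbind(0.003 * cos(runif(3000, 0, 2 * pi)),
                0.003 * sin(runif(3000, 0, 2 * pi)),
                runif(3000, 0, 0.3))
  mkbranch <- function(z, az) {
    t <- runif(400, 0, 0.05)
    cbind(t * cos(az) + 0.0015 * rnorm(400),
          t * sin(az) + 0.0015 * rnorm(400), z + 0.0015 * rnorm(400))
  }
  pts <- rbind(stem, mkbranch(0.06, 0), mkbranch(0.06, pi),
               mkbranch(0.12, pi / 3), mkbranch(0.18, 4))
  nd <- detect_cotyledon_node(point_cloud(pts))
  expect_equal(nd$confidence, "ok")
  expect_lte(abs(nd$z_fn - 0.06), 0.01)
  expect_gte(length(nd$nodes), 2)
})

test_that("a leafless vertical stem yields a low-confidence fallback", {
  set.seed(85)
  stem <- cbind(0.003 * cos(runif(2000, 0, 2 * pi)),
                0.003 * sin(runif(2000, 0, 2 * pi)),
                runif(2000, 0, 0.3))
  nd <- detect_cotyledon_node(point_cloud(stem))
  expect_equal(nd$confidence, "low")
  expect_error(detect_cotyledon_node(random_cloud(50)), "too small")
})

test_that("leaf segmentation counts generator laminae", {
  set.seed(86)
  hits <- 0
  for (i in 1:10) {
    nl <- sample(4:6, 1)
    pl <- generate_plant(c(0, 0), 0.3, 0.07, nl, noise_sigma = 0,
                         n_points = 3000)
    lv <- segment_leaves(point_cloud(pl$points))
    hits <- hits + (length(lv) == nl)
  }
  expect_gte(hits, 9)
})

test_that("a bare stem has zero leaves", {
  set.seed(87)
  stem <- cbind(0.004 * cos(runif(2000, 0, 2 * pi)),
                0.004 * sin(runif(2000, 0, 2 * pi)),
                runif(2000, 0, 0.3))
  expect_length(segment_leaves(point_cloud(stem)), 0L)
})

test_that("parallel but disjoint blades stay separate clusters", {
  set.seed(88)
  b1 <- cbind(runif(800, 0, 0.04), runif(800, 0, 0.03), 0.10)
  b2 <- cbind(runif(800, 0.08, 0.12), runif(800, 0, 0.03), 0.10)
  lv <- segment_leaves(point_cloud(rbind(b1, b2) +
                                     matrix(rnorm(4800, sd = 5e-4), ncol = 3)))
  expect_length(lv, 2L)
})

test_that("leaf area recovers analytic areas of reference shapes", {
  set.seed(89)
  th <- runif(2000, 0, 2 * pi)
  rr <- 0.03 * sqrt(runif(2000))
  disc <- cbind(rr * cos(th), rr * sin(th), 0)
  a <- leaf_area(disc)
  expect_equal(a$flag, "")
  expect_lt(abs(a$area - pi * 0.03^2) / (pi * 0.03^2), 0.05)

  sq <- cbind(runif(20000), runif(20000), 0)
  expect_lt(abs(leaf_area(sq)$area - 1), 0.02)

  expect_error(leaf_area(disc[1:10, ]), "at least 30")
})

test_that("leaf area is stable under doubled sampling density", {
  set.seed(90)
  mkdisc <- function(n) {
    th <- runif(n, 0, 2 * pi)
    rr <- 0.03 * sqrt(runif(n))
    cbind(rr * cos(th), rr * sin(th), 0)
  }
  a1 <- leaf_area(mkdisc(2000))$area
  a2 <- leaf_area(mkdisc(4000))$area
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("trait extraction produces consistent per-plant records", {
  fld <- generate_field(field_spec(seed = 91))
  res <- run_pipeline(fld$cloud, level = FALSE, variety = "VARf6",
                      plot = "a")
  tr <- res$traits
  expect_equal(nrow(tr), 9L)
  expect_true(all(is.finite(tr$ph_m)))
  expect_true(all(is.finite(tr$fcnh_m)))
  expect_true(all(tr$ph_m > 0))
  expect_true(all(tr$fcnh_m > 0))
  la <- attr(tr, "leaf_areas")
  for (r in seq_len(nrow(tr)))
    expect_equal(tr$leaf_area_total_m2[r], sum(la[[r]]), tolerance = 1e-9)
  # FCNH/PH arithmetic against the stored datums
  expect_equal(tr$fcnh_m, tr$z_fn - tr$z_gd, tolerance = 1e-12)
  expect_equal(tr$ph_m, tr$z_msv - tr$z_gd, tolerance = 1e-12)
  expect_equal(tr$ph_from_node_m, tr$z_msv - tr$z_fn, tolerance = 1e-12)
})

test_that("traits are invariant to rigid translation of the scene", {
  fld <- generate_field(field_spec(rows = 1, cols = 2, seed = 92))
  shift <- c(1.5, -2, 0.4)
  cl2 <- fld$cloud
  cl2$points <- sweep(cl2$points, 2, shift, "+")
  r1 <- run_pipeline(fld$cloud, level = FALSE, traits = TRUE)
  # leveling restores z = 0 ground for the shifted scene
  r2 <- run_pipeline(cl2, level = TRUE, traits = TRUE)
  expect_equal(r2$traits$ph_m, r1$traits$ph_m, tolerance = 0.005)
  expect_equal(r2$traits$fcnh_m, r1$traits$fcnh_m, tolerance = 0.005)
})
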