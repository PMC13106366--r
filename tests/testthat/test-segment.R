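test_that("normal estimation is exact on a plane and radial on a sphere", {
  set.seed(61)
  pl <- point_cloud(cbind(runif(2000), runif(2000), 0))
  e <- estimate_normals_curvature(pl, 15)
  expect_lt(max(abs(abs(e$normals[, 3]) - 1)), 1e-6)
  expect_lt(max(e$curvatures), 1e-9)

  dirs <- matrix(rnorm(15000), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sph <- point_cloud(0.05 * dirs)
  es <- estimate_normals_curvature(sph, 15)
  ang <- acos(pmin(abs(rowSums(es$normals * dirs)), 1)) * 180 / pi
  expect_lt(quantile(ang, 0.99), 3)

  blob <- point_cloud(matrix(rnorm(1500, sd = 0.02), ncol = 3))
  eb <- estimate_normals_curvature(blob, 15)
  expect_lt(median(e$curvatures), median(es$curvatures))
  expect_lt(median(es$curvatures), median(eb$curvatures))
})

test_that("region height is the cylinder-restricted maximum z", {
  pts <- rbind(c(0, 0, 0.05), c(0.01, 0, 0.31), c(0.1, 0, 0.4))
  gp <- point_cloud(pts)
  expect_equal(region_height(gp, c(0, 0, 0.06), d_cyl = 0.03), 0.31)
  expect_error(region_height(gp, c(5, 5, 0.06), d_cyl = 0.03), "no points")
})

test_that("constraint region geometry follows r_k = R_hk tan(alpha)", {
  r <- make_constraint_region(c(0, 0, 0.05), r_hk = 0.30, alpha = 35,
                              z_min = 0.01)
  expect_equal(r$r_k, 0.2101, tolerance = 1e-3)
  expect_equal(r$r_k, 0.30 * tan(35 * pi / 180), tolerance = 1e-12)
  tiny <- make_constraint_region(c(0, 0, 0), 0.30, alpha = 1e-6)
  expect_lt(tiny$r_k, 1e-8)
  expect_error(make_constraint_region(c(0, 0, 0), 0.3, alpha = 90), "alpha")

  inside <- c(0.20, 0, 0.05)
  below <- c(0.20, 0, 0.005)
  outside <- c(0.22, 0, 0.05)
  m <- region_contains(r, rbind(inside, below, outside))
  expect_equal(unname(m), c(TRUE, FALSE, FALSE))
})

test_that("growth labels an isolated plant fully and no ground", {
  fld <- generate_field(field_spec(rows = 1, cols = 1, seed = 62))
  sp <- hcsf_split(fld$cloud)
  gp <- estimate_normals_curvature(sp$gp, 20)
  reg <- locate_plants(gp)
  lab <- segment_population(gp, reg)
  gt <- fld$cloud$labels[attr(gp, "source_indices")]
  plant_pts <- gt == 1L
  expect_gte(mean(lab$labels[plant_pts] == 1L), 0.99)
  expect_equal(sum(lab$labels[!plant_pts] != 0L), 0L)
})

test_that("a point beyond delta from all growth fronts stays unassigned", {
  set.seed(63)
  stem <- cbind(rnorm(300, sd = 0.002), rnorm(300, sd = 0.002),
                runif(300, 0, 0.2))
  lonely <- c(0.05, 0, 0.1)  # 5 cm away, delta = 1.5 cm
  pc <- estimate_normals_curvature(point_cloud(rbind(stem, lonely)), 10)
  reg <- list(make_constraint_region(c(0, 0, 0.06), 0.2, 35, 0))
  lab <- grow_instances(pc, list(which(stem[, 3] < 0.05)), reg)
  expect_equal(lab$labels[301], 0L)
  expect_gte(mean(lab$labels[1:300] == 1L), 0.99)
})

test_that("disjoint constraint regions can produce no contested points", {
  fld <- generate_field(field_spec(rows = 1, cols = 2, seed = 64,
                                   overlap_factor = 0))
  sp <- hcsf_split(fld$cloud)
  gp <- estimate_normals_curvature(sp$gp, 20)
  reg <- locate_plants(gp)
  params <- growth_params()
  z_min <- min(gp$points[, 3])
  regions <- list()
  seeds <- list()
  for (r in 1:2) {
    a <- c(reg$x[r], reg$y[r], reg$z[r])
    incyl <- (gp$points[, 1] - a[1])^2 + (gp$points[, 2] - a[2])^2 <=
      params$d_cyl^2
    # artificially small disjoint regions (plants are 10 cm apart)
    regions[[r]] <- make_constraint_region(a, 0.04 / tan(35 * pi / 180),
                                           35, z_min)
    seeds[[r]] <- which(incyl & gp$points[, 3] <= a[3])
  }
  lab <- grow_instances(gp, seeds, regions, params)
  expect_length(lab$contested, 0L)
  both <- table(lab$labels[lab$labels > 0])
  expect_length(both, 2L)
})

test_that("growth matches the round-synchronous brute-force reference", {
  set.seed(65)
  for (rep in 1:3) {
    fld <- generate_field(field_spec(rows = 1, cols = 2, seed = 65 + rep,
                                     points_per_plant = 800,
                                     ground_points = 500,
                                     overlap_factor = 1.2))
    sp <- hcsf_split(fld$cloud)
    gp <- estimate_normals_curvature(sp$gp, 15)
    reg <- locate_plants(gp, min_cluster_size = 6)
    params <- growth_params()
    z_min <- min(gp$points[, 3])
    regions <- list()
    seeds <- list()
    for (r in seq_len(nrow(reg))) {
      a <- c(reg$x[r], reg$y[r], reg$z[r])
      incyl <- (gp$points[, 1] - a[1])^2 + (gp$points[, 2] - a[2])^2 <=
        params$d_cyl^2
      regions[[r]] <- make_constraint_region(
        a, max(gp$points[incyl, 3]), params$alpha, z_min)
      seeds[[r]] <- which(incyl & gp$points[, 3] <= a[3])
    }
    fast <- grow_instances(gp, seeds, regions, params)
    labels0 <- integer(n_points(gp))
    for (k in seq_along(seeds)) labels0[seeds[[k]]] <- k
    slow <- brute_grow(gp$points, gp$normals, labels0,
                       t(vapply(regions, function(r) r$a_pk[1:2],
                                numeric(2))),
                       vapply(regions, function(r) r$r_k^2, numeric(1)),
                       z_min, params$delta, params$tau_n)
    expect_identical(as.integer(fast$labels), as.integer(slow$labels))
    expect_identical(as.integer(fast$contested), as.integer(slow$contested))
    expect_identical(lapply(fast$claims, as.integer), slow$claims)
  }
})

test_that("enlarging delta does not shrink the reached point set", {
  fld <- generate_field(field_spec(seed = 66))
  sp <- hcsf_split(fld$cloud)
  gp <- estimate_normals_curvature(sp$gp, 20)
  reg <- locate_plants(gp)
  reached <- function(delta) {
    lab <- segment_population(gp, reg, growth_params(delta = delta))
    sum(lab$labels > 0)
  }
  r1 <- reached(0.012)
  r2 <- reached(0.015)
  r3 <- reached(0.020)
  expect_lte(r1, r2)
  expect_lte(r2, r3)
})

test_that("overlap resolution honors plane distance in the trivial case", {
  set.seed(67)
  # plant 1 blade at z = 0.10, plant 2 blade at z = 0.12; contested point
  # exactly on plant 1's plane, 0.02 m off plant 2's
  b1 <- cbind(runif(300, -0.03, 0), runif(300, -0.02, 0.02), 0.10)
  b2 <- cbind(runif(300, 0.005, 0.035), runif(300, -0.02, 0.02), 0.12)
  q <- c(0.002, 0, 0.10)
  pc <- estimate_normals_curvature(point_cloud(rbind(b1, b2, q)), 10)
  labeling <- structure(list(labels = c(rep(1L, 300), rep(2L, 300), 0L),
                             contested = 601L, claims = list(c(1L, 2L))),
                        class = "instance_labeling")
  out <- resolve_overlaps(pc, labeling, growth_params(gamma2 = 0.005))
  expect_equal(out$labels[601], 1L)
  expect_length(out$contested, 0L)
})

test_that("resolution is the identity when nothing is contested", {
  lab <- structure(list(labels = c(1L, 1L, 2L), contested = integer(0),
                        claims = list()), class = "instance_labeling")
  pc <- estimate_normals_curvature(random_cloud(40, seed = 68), 10)
  out <- resolve_overlaps(pc, lab, growth_params())
  expect_identical(out$labels, lab$labels)
})

test_that("a contested band between stacked blades resolves to true owners", {
  set.seed(69)
  # two interpenetrating near-parallel blades, 8 mm apart in z; the seam
  # band (symmetric wave arrival) is contested between both plants
  mk <- function(n, x0, x1, z) cbind(runif(n, x0, x1),
                                     runif(n, -0.02, 0.02), z)
  b1 <- mk(2500, -0.06, 0.02, 0.100)
  b2 <- mk(2500, -0.02, 0.06, 0.108)
  pts <- rbind(b1, b2) + matrix(rnorm(15000), ncol = 3) * 0.0008
  gt <- rep(c(1L, 2L), each = 2500)
  pc <- estimate_normals_curvature(point_cloud(pts), 20)
  contested <- which(abs(pts[, 1]) < 0.005)
  labels <- gt
  labels[contested] <- 0L
  labeling <- structure(
    list(labels = labels, contested = contested,
         claims = rep(list(c(1L, 2L)), length(contested))),
    class = "instance_labeling")
  rl <- resolve_overlaps(pc, labeling, growth_params())
  expect_gt(length(contested), 100)
  cas <- rl$labels[contested]
  cgt <- gt[contested]
  expect_gte(mean(cas > 0), 0.9)
  expect_gte(mean(cas[cas > 0] == cgt[cas > 0]), 0.9)
  expect_length(rl$contested, 0L)
})

test_that("population segmentation is complete, contained and partitioned", {
  fld <- generate_field(field_spec(seed = 70))
  sp <- hcsf_split(fld$cloud)
  gp <- estimate_normals_curvature(sp$gp, 20)
  reg <- locate_plants(gp)
  lab <- segment_population(gp, reg)
  expect_equal(sort(unique(lab$labels[lab$labels > 0])), 1:9)
  expect_length(lab$contested, 0L)
  # exact containment of every labeled point in its constraint region
  for (k in 1:9) {
    idx <- which(lab$labels == k)
    expect_true(all(region_contains(lab$regions[[as.character(k)]],
                                    gp$points[idx, , drop = FALSE])))
  }
})

test_that("segmentation is invariant to point order", {
  fld <- generate_field(field_spec(rows = 1, cols = 2, seed = 71,
                                   points_per_plant = 1200,
                                   ground_points = 4000))
  sp <- hcsf_split(fld$cloud)
  gp <- estimate_normals_curvature(sp$gp, 20)
  reg <- locate_plants(gp)
  lab <- segment_population(gp, reg)
  set.seed(71)
  perm <- sample.int(n_points(gp))
  gp2 <- subset_cloud(gp, perm)
  lab2 <- segment_population(gp2, reg)
  expect_identical(as.integer(lab2$labels), as.integer(lab$labels[perm]))
})
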