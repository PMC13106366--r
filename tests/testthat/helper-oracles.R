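# Independent reference implementations (brute force, O(n^2)) and printed
# evaluation tables used as fixed inputs across tests.

# DBSCAN with the same deterministic conventions as the package:
# core = |N_eps| >= min_pts (self included); clusters = components of the
# core-core graph numbered by smallest member; border -> lowest cluster id.
brute_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  core <- rowSums(D <= eps) >= min_pts
  comp <- integer(n)
  id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || comp[i] != 0L) next
    id <- id + 1L
    q <- i
    comp[i] <- id
    while (length(q)) {
      p <- q[1]
      q <- q[-1]
      nb <- which(core & comp == 0L & D[p, ] <= eps)
      comp[nb] <- id
      q <- c(q, nb)
    }
  }
  lab <- comp
  for (i in which(!core)) {
    nb <- which(core & D[i, ] <= eps)
    lab[i] <- if (length(nb)) min(comp[nb]) else 0L
  }
  lab
}

# statistical outlier removal by full distance matrix
brute_sor <- function(pts, k, std_mult) {
  D <- as.matrix(dist(pts))
  md <- apply(D, 1, function(r) mean(sort(r)[2:(k + 1)]))
  unname(which(md <= mean(md) + std_mult * sd(md)))
}

# region growing reference: plant-synchronous rounds, rescanning all points
# every round; contested points freeze with their claimant sets
brute_grow <- function(pts, normals, labels0, centers, radius2, z_min,
                       delta, tau_n) {
  n <- nrow(pts)
  labels <- labels0
  contested <- logical(n)
  claims <- vector("list", n)
  K <- nrow(centers)
  frontier <- lapply(seq_len(K), function(k) which(labels0 == k))
  repeat {
    claimed <- vector("list", n)
    for (k in seq_len(K)) {
      for (p in frontier[[k]]) {
        d2 <- colSums((t(pts) - pts[p, ])^2)
        cand <- which(d2 <= delta^2 & labels == 0L & !contested &
                        seq_len(n) != p)
        for (q in cand) {
          if ((pts[q, 1] - centers[k, 1])^2 +
              (pts[q, 2] - centers[k, 2])^2 > radius2[k]) next
          if (pts[q, 3] < z_min) next
          if (abs(sum(normals[p, ] * normals[q, ])) < tau_n) next
          claimed[[q]] <- union(claimed[[q]], k)
        }
      }
    }
    frontier <- lapply(seq_len(K), function(k) integer(0))
    any_lab <- FALSE
    for (q in which(lengths(claimed) > 0)) {
      ks <- claimed[[q]]
      if (length(ks) == 1L) {
        labels[q] <- ks
        frontier[[ks]] <- c(frontier[[ks]], q)
        any_lab <- TRUE
      } else {
        contested[q] <- TRUE
        claims[[q]] <- sort(ks)
      }
    }
    if (!any_lab) break
  }
  list(labels = labels, contested = which(contested),
       claims = claims[contested])
}

# printed per-plot instance-detection tables (inputs: plot id, manually
# counted, divided, FP, FN, TP, and the printed r/p/F percentages)
table4 <- data.frame(
  variety = rep(c("VARc94", "VARf6", "VARx36"), each = 3),
  rep = rep(c("a", "b", "c"), 3),
  fp = c(3, 4, 5, 3, 3, 4, 5, 4, 4),
  fn = c(5, 3, 5, 4, 4, 3, 3, 3, 5),
  tp = c(40, 41, 40, 41, 40, 41, 43, 42, 40),
  r = c(88.89, 93.18, 88.89, 91.11, 90.91, 93.18, 93.48, 93.33, 88.89),
  p = c(93.02, 91.11, 88.89, 93.18, 93.02, 91.11, 89.58, 91.30, 90.91),
  f = c(90.91, 92.13, 88.89, 92.13, 91.95, 92.13, 91.49, 92.31, 89.89)
)

table6_ours <- data.frame(
  variety = c("VARc94", "VARf6", "VARx36"),
  fp = c(12, 10, 13),
  fn = c(13, 11, 11),
  tp = c(121, 122, 125),
  r = c(90.30, 91.73, 91.91),
  p = c(90.98, 92.42, 90.58),
  f = c(90.64, 92.08, 91.24)
)

random_cloud <- function(n, labeled = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point_cloud(matrix(runif(3 * n, -1, 1), n),
              matrix(runif(3 * n), n),
              labels = if (labeled) sample(0:3, n, replace = TRUE))
}

# minimal ASCII splat-scene PLY
write_splat_ply <- function(path, mu, log_scale, rot, opacity_logit, f_dc) {
  n <- nrow(mu)
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
           paste("property float",
                 c("x", "y", "z", paste0("f_dc_", 0:2), "opacity",
                   paste0("scale_", 0:2), paste0("rot_", 0:3))),
           "end_header")
  rows <- apply(cbind(mu, f_dc, opacity_logit, log_scale, rot), 1,
                function(r) paste(sprintf("%.9g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  path
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
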