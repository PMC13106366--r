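# End-to-end orchestration: scene leveling, denoising, ground/plant
# separation, localization, constrained instance segmentation, traits.
# Also the one-at-a-time parameter sensitivity protocol used to verify
# robustness of the segmentation to its core parameters.

#' Run the full phenotyping pipeline on a field scene
#'
#' Steps: (optional) RANSAC ground-plane leveling; statistical outlier
#' removal and bilateral smoothing; hue-enhanced cloth-simulation split
#' into ground and plants; stem-layer localization; dynamically
#' constrained instance segmentation; per-plant trait extraction.
#'
#' @param cloud input [point_cloud] (colored field scene).
#' @param params a [growth_params] object.
#' @param tparams a [trait_params] object.
#' @param level run ground-plane leveling (disable for already-aligned
#'   scenes).
#' @param denoise run SOR + bilateral smoothing.
#' @param traits extract traits (disable for segmentation-only runs).
#' @param variety,plot registry identity.
#' @param seed seed for the RANSAC plane proposals.
#' @return list with `cloud` (cleaned), `gp`, `gs`, `registry`,
#'   `labeling`, `full_labels` (labels mapped back onto the input cloud;
#'   points removed by denoising stay 0) and `traits` (data.frame or NULL).
#' @export
run_pipeline <- function(cloud, params = growth_params(),
                         tparams = trait_params(), level = TRUE,
                         denoise = TRUE, traits = TRUE,
                         variety = "unknown", plot = "unknown", seed = 1L) {
  n_in <- n_points(cloud)
  attr(cloud, "source_indices") <- seq_len(n_in)
  work <- cloud
  if (level) work <- level_scene(work, seed = seed)$cloud
  if (denoise) {
    work <- remove_statistical_outliers(work, k = 20L, std_mult = 2)
    work <- bilateral_smooth(work, k = 20L)
  }
  split <- hcsf_split(work)
  gp <- estimate_normals_curvature(split$gp, params$k_normals)
  registry <- locate_plants(gp, layer = params$layer, eps = params$eps,
                            min_pts = params$min_pts, variety = variety,
                            plot = plot)
  labeling <- segment_population(gp, registry, params)
  full_labels <- integer(n_in)
  full_labels[attr(gp, "source_indices")] <- labeling$labels
  tr <- if (traits)
    extract_traits(labeling, gp, split$gs, registry, tparams) else NULL
  list(cloud = work, gp = gp, gs = split$gs, registry = registry,
       labeling = labeling, full_labels = full_labels, traits = tr)
}

# admissible ranges for the core segmentation parameters (grid-search
# bounds of the tuning protocol); one-at-a-time variations are clipped
# to these
.param_ranges <- list(
  eps = c(0.008, 0.020), min_pts = c(3, 10), d_cyl = c(0.020, 0.040),
  alpha = c(20, 50), delta = c(0.010, 0.030), tau_n = c(0.70, 0.95)
)

#' One-at-a-time parameter sensitivity of segmentation mIoU
#'
#' On a fixed labeled scene, reruns localization + segmentation with each
#' core parameter (eps, MinPts, d, alpha, delta, tau_N) varied by
#' `+/- rel` around its default, one at a time, clipping each variation to
#' the parameter's admissible tuning range (MinPts is rounded to an
#' integer). Reports the mIoU of every run against the ground-truth labels
#' and the maximum absolute change from the default run.
#'
#' Denoising, the ground/plant split and normal estimation do not depend
#' on the varied parameters and are computed once.
#'
#' @param cloud labeled [point_cloud] (ground truth in `labels`), already
#'   aligned.
#' @param params baseline [growth_params].
#' @param rel relative variation (default 0.2 = +/-20%).
#' @param denoise run SOR + bilateral first (default TRUE).
#' @return list with `runs` (data.frame: parameter, value, miou),
#'   `miou_default`, and `max_abs_change_pp` (percentage points).
#' @export
parameter_sensitivity <- function(cloud, params = growth_params(),
                                  rel = 0.2, denoise = TRUE) {
  if (is.null(cloud$labels)) stop("cloud must carry ground-truth labels")
  n_in <- n_points(cloud)
  attr(cloud, "source_indices") <- seq_len(n_in)
  work <- cloud
  if (denoise) {
    work <- remove_statistical_outliers(work, k = 20L, std_mult = 2)
    work <- bilateral_smooth(work, k = 20L)
  }
  split <- hcsf_split(work)
  gp <- estimate_normals_curvature(split$gp, params$k_normals)
  gp_src <- attr(gp, "source_indices")

  run_once <- function(p) {
    reg <- locate_plants(gp, layer = p$layer, eps = p$eps,
                         min_pts = p$min_pts)
    lab <- segment_population(gp, reg, p)
    pred <- integer(n_in)
    pred[gp_src] <- lab$labels
    miou(pred, cloud$labels)
  }

  base <- run_once(params)
  runs <- data.frame(parameter = "default", value = NA_real_, miou = base)
  for (nm in names(.param_ranges)) {
    for (sgn in c(-1, 1)) {
      val <- params[[nm]] * (1 + sgn * rel)
      rng <- .param_ranges[[nm]]
      val <- min(max(val, rng[1]), rng[2])
      if (nm == "min_pts") val <- as.integer(round(val))
      p2 <- params
      p2[[nm]] <- val
      runs <- rbind(runs, data.frame(parameter = nm, value = val,
                                     miou = run_once(p2)))
    }
  }
  list(runs = runs, miou_default = base,
       max_abs_change_pp = 100 * max(abs(runs$miou - base)))
}
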