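# Scoring of instance labelings against ground truth (TP/FP/FN, recall,
# precision, F, per-instance IoU, mIoU) and convex-hull point-density
# metrics. A predicted instance counts as a detection (TP) when its
# point-set IoU with its greedily matched truth instance reaches iou_min.

as_label_vector <- function(x) {
  if (inherits(x, "instance_labeling")) x$labels else as.integer(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Confusion counts
#' @param tp,fp,fn non-negative integers.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)), class = "confusion_counts")
}

#' Match predicted and truth instances
#'
#' Greedy one-to-one matching by descending point-set IoU over the same
#' underlying cloud. A truth plant whose match reaches `iou_min` is a true
#' positive; predictions left unmatched (or matched below the threshold)
#' are false positives, truth plants likewise false negatives.
#'
#' @param pred,gt instance labelings (`instance_labeling` objects or
#'   integer label vectors of equal length; label 0 = background).
#' @param iou_min IoU threshold for a detection (default 0.5).
#' @return list with `counts` ([confusion_counts]) and `matches`
#'   (data.frame `pred`, `gt`, `iou`, `tp`).
#' @export
match_instances <- function(pred, gt, iou_min = 0.5) {
  p <- as_label_vector(pred)
  g <- as_label_vector(gt)
  if (length(p) != length(g)) stop("labelings cover different clouds")
  pk <- sort(unique(p[p > 0L]))
  gk <- sort(unique(g[g > 0L]))
  if (length(pk) && length(gk)) {
    inter <- table(factor(p, levels = pk)[p > 0L & g > 0L],
                   factor(g, levels = gk)[p > 0L & g > 0L])
    np <- tabulate(match(p, pk), nbins = length(pk))
    ng <- tabulate(match(g, gk), nbins = length(gk))
    iou <- as.matrix(inter) /
      (outer(np, ng, "+") - as.matrix(inter))
  } else {
    iou <- matrix(0, length(pk), length(gk))
  }
  ord <- order(iou, decreasing = TRUE)
  used_p <- logical(length(pk))
  used_g <- logical(length(gk))
  rows <- list()
  for (o in ord) {
    if (iou[o] <= 0) break
    i <- (o - 1L) %% length(pk) + 1L
    j <- (o - 1L) %/% length(pk) + 1L
    if (used_p[i] || used_g[j]) next
    used_p[i] <- used_g[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(pred = pk[i], gt = gk[j],
                                            iou = iou[o])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  matches$tp <- matches$iou >= iou_min
  tp <- sum(matches$tp)
  list(counts = confusion_counts(tp, length(pk) - tp, length(gk) - tp),
       matches = matches)
}

#' Recall, precision and F score from confusion counts
#'
#' r = 100 tp / (tp + fn), p = 100 tp / (tp + fp), F = 2pr / (p + r),
#' reported as percentages rounded half-up to 2 decimals (F computed from
#' the unrounded r and p).
#'
#' @param c a [confusion_counts] (or list with tp, fp, fn).
#' @return named numeric vector `c(r, p, f)` in percent.
#' @export
prf <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp + fn == 0 || tp + fp == 0)
    stop("prf undefined: zero positives on one side")
  r <- 100 * tp / (tp + fn)
  p <- 100 * tp / (tp + fp)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  round_half_up(c(r = r, p = p, f = f), 2)
}

#' Micro-aggregated recall/precision/F over several plots
#'
#' Sums the confusion counts and applies [prf] to the totals.
#'
#' @param counts list of [confusion_counts].
#' @return named numeric vector `c(r, p, f)` in percent.
#' @export
aggregate_micro <- function(counts) {
  if (!length(counts)) stop("no counts to aggregate")
  tot <- confusion_counts(sum(vapply(counts, `[[`, integer(1), "tp")),
                          sum(vapply(counts, `[[`, integer(1), "fp")),
                          sum(vapply(counts, `[[`, integer(1), "fn")))
  prf(tot)
}

#' Mean IoU over matched instances
#'
#' @param pred,gt as in [match_instances].
#' @param matches optional precomputed match table; recomputed when absent.
#' @return mean IoU in \[0, 1\]; 0 when nothing matched.
#' @export
miou <- function(pred, gt, matches = NULL) {
  if (is.null(matches)) matches <- match_instances(pred, gt)$matches
  if (!nrow(matches)) return(0)
  mean(matches$iou)
}

#' Convex-hull point-density metrics
#'
#' Surface density D_sur = N / A_cs (points per mm^2 of hull surface) and
#' volume density D_vol = N / V_cv (points per mm^3 of hull volume);
#' coordinates are converted from meters to millimeters.
#'
#' @param cloud a [point_cloud] (or m x 3 matrix, meters) with at least 4
#'   non-coplanar points.
#' @return list with `n`, `a_cs` (mm^2), `v_cv` (mm^3), `d_sur`, `d_vol`.
#' @export
density_metrics <- function(cloud) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else
    as_xyz_matrix(cloud, "cloud")
  hull <- convex_hull_3d(pts * 1000)
  n <- nrow(pts)
  list(n = n, a_cs = hull$area, v_cv = hull$volume,
       d_sur = n / hull$area, d_vol = n / hull$volume)
}

#' Full segmentation score against ground truth
#'
#' Convenience wrapper returning detection metrics and mIoU in one call.
#'
#' @inheritParams match_instances
#' @return list with `counts`, `r`, `p`, `f` (percent), `matches`, `miou`.
#' @export
seg_metrics <- function(pred, gt, iou_min = 0.5) {
  m <- match_instances(pred, gt, iou_min)
  s <- prf(m$counts)
  list(counts = m$counts, r = s["r"], p = s["p"], f = s["f"],
       matches = m$matches, miou = miou(NULL, NULL, m$matches))
}
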