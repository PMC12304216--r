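# Evaluation metrics: Dice overlap, centerline accuracy (fraction of the
# ground-truth length recovered within tolerance), and the mean centerline
# distance (symmetric average of directed mean nearest-neighbour distances).

#' Dice coefficient between two voxel sets
#'
#' `2|X intersect Y| / (|X| + |Y|)` on boolean grids of identical shape.
#' Two empty sets are defined to have Dice 1 (perfect agreement on "nothing").
#'
#' @param x,y Logical/0-1 arrays of identical dimensions (prediction and
#'   annotation).
#' @return Numeric in \[0, 1\].
#' @export
dice_coefficient <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("grid mismatch between voxel sets")
  x <- as.logical(x); y <- as.logical(y)
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0) return(1.0)
  2 * sum(x & y) / (nx + ny)
}

#' Per-label Dice between two label masks
#'
#' @param pred,truth [vwi_mask] objects on the same grid.
#' @return data.frame with artery, side and Dice per label present in either
#'   mask (matched on artery + side).
#' @export
dice_per_label <- function(pred, truth) {
  if (!identical(dim(pred$data), dim(truth$data)))
    stop("grid mismatch between masks")
  keys <- unique(rbind(truth$labels[c("artery", "side")],
                       pred$labels[c("artery", "side")]))
  res <- lapply(seq_len(nrow(keys)), function(r) {
    a <- keys$artery[r]; s <- keys$side[r]
    data.frame(artery = a, side = s,
               dice = dice_coefficient(mask_binary(pred, a, s),
                                       mask_binary(truth, a, s)))
  })
  do.call(rbind, res)
}

# Directed mean nearest-neighbour distance helpers (chunked to bound memory).
nn_min_dist <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  b2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  chunk <- max(1L, as.integer(2e6 / max(1, nrow(b))))
  for (lo in seq(1, nrow(a), by = chunk)) {
    hi <- min(nrow(a), lo + chunk - 1)
    aa <- a[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), b2, "+") - 2 * aa %*% t(b)
    out[lo:hi] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Mean centerline distance (MCD)
#'
#' Symmetric average of the two directed mean nearest-neighbour distances
#' between the annotated point set `s_g` and the predicted point set `s_p`:
#' half the sum of (mean over annotated points of the distance to the nearest
#' predicted point) and (mean over predicted points of the distance to the
#' nearest annotated point), Euclidean, in mm.
#'
#' Centerline inputs are arc-length resampled first (`sample_mm`) so the
#' result does not depend on control-point density; set `sample_mm = NULL`
#' to use the raw points.
#'
#' @param s_g,s_p [vwi_centerline] objects or n x 3 matrices of mm points.
#' @param sample_mm Resampling step for centerline inputs (default 0.5 mm).
#' @return MCD in mm.
#' @export
mcd <- function(s_g, s_p, sample_mm = 0.5) {
  as_pts <- function(x) {
    if (inherits(x, "vwi_centerline")) {
      if (!is.null(sample_mm)) resample_polyline(x$points, sample_mm)
      else x$points
    } else matrix(x, ncol = 3)
  }
  g <- as_pts(s_g); p <- as_pts(s_p)
  if (nrow(g) == 0 || nrow(p) == 0) stop("MCD of an empty point set")
  0.5 * (mean(nn_min_dist(g, p)) + mean(nn_min_dist(p, g)))
}

#' Centerline accuracy
#'
#' Ratio of accurately extracted centerline length to ground-truth centerline
#' length: the arc length of the extracted line lying within `tol_mm` of the
#' truth polyline, divided by the truth's arc length, capped at 1.
#'
#' @param extracted,truth [vwi_centerline] objects (or n x 3 mm matrices,
#'   interpreted as polylines).
#' @param tol_mm Distance tolerance defining "accurately extracted"
#'   (default 1 mm).
#' @param sample_mm Evaluation sampling step along the extracted line.
#' @return Numeric in \[0, 1\].
#' @export
centerline_accuracy <- function(extracted, truth, tol_mm = 1, sample_mm = 0.1) {
  pts_of <- function(x) if (inherits(x, "vwi_centerline")) x$points else
    matrix(x, ncol = 3)
  e <- pts_of(extracted); t_ <- pts_of(truth)
  if (nrow(e) == 0 || nrow(t_) == 0) stop("empty centerline")
  tlen <- tail(polyline_arclength(t_), 1)
  if (tlen <= 0) stop("zero-length ground-truth centerline")
  es <- resample_polyline(e, sample_mm)
  elen <- tail(polyline_arclength(es), 1)
  if (elen <= 0) return(0)
  d <- min_dist_to_polyline(es, t_)
  good_len <- elen * mean(d <= tol_mm)
  min(1, good_len / tlen)
}

#' Match predicted and truth centerlines and evaluate
#'
#' Pairs centerlines by artery + side and reports MCD and centerline accuracy
#' per pair; unmatched truth lines get NA.
#'
#' @param pred,truth Lists of [vwi_centerline].
#' @param tol_mm Tolerance for [centerline_accuracy()].
#' @param sample_mm Resampling step for [mcd()].
#' @return data.frame with artery, side, mcd_mm, centerline_accuracy.
#' @export
evaluate_centerlines <- function(pred, truth, tol_mm = 1, sample_mm = 0.5) {
  keyof <- function(cl) paste(cl$label, cl$side)
  pk <- vapply(pred, keyof, "")
  res <- lapply(truth, function(tr) {
    hit <- which(pk == keyof(tr))
    if (length(hit) == 0)
      return(data.frame(artery = tr$label, side = tr$side, mcd_mm = NA_real_,
                        centerline_accuracy = 0))
    # several fragments with the same key: evaluate against their union
    pts <- do.call(rbind, lapply(pred[hit], function(p)
      resample_polyline(p$points, sample_mm)))
    m <- mcd(resample_polyline(tr$points, sample_mm), pts, sample_mm = NULL)
    acc <- max(vapply(pred[hit], function(p)
      centerline_accuracy(p, tr, tol_mm = tol_mm), 0))
    data.frame(artery = tr$label, side = tr$side, mcd_mm = m,
               centerline_accuracy = acc)
  })
  do.call(rbind, res)
}
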