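# Core containers. Geometry conventions used throughout:
#   - volumes are R arrays dim (nx, ny, nz); axis 1 = x = left-right,
#     axis 3 = z = inferior -> superior
#   - world coordinates (mm) = (1-based voxel index - 1) * spacing;
#     i.e. voxel centres sit on an axis-aligned grid starting at the origin
#   - all centerline points are stored in world mm

#' Create a 3D scalar volume
#'
#' @param data 3D numeric array (nx, ny, nz).
#' @param spacing Per-axis voxel size in mm (length 3).
#' @param kind Sequence kind, one of [sequence_kinds()] or `"other"`.
#' @return A `vwi_volume` object.
#' @export
vwi_volume <- function(data, spacing, kind = "other") {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing), kind = kind),
            class = "vwi_volume")
}

#' @export
print.vwi_volume <- function(x, ...) {
  cat(sprintf("<vwi_volume %s  %s voxels  spacing %s mm>\n", x$kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Create a multi-label vessel mask
#'
#' Label 0 is background; positive integers index rows of `labels`, a table
#' mapping label id to artery class and side.
#'
#' @param data 3D integer array of label ids.
#' @param spacing Per-axis voxel size in mm.
#' @param labels data.frame with columns `id`, `artery`, `side`
#'   (side in `"left"`, `"right"`, `"midline"`).
#' @return A `vwi_mask` object.
#' @export
vwi_mask <- function(data, spacing, labels) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3)
  stopifnot(all(c("id", "artery", "side") %in% names(labels)))
  bad <- setdiff(unique(labels$artery), artery_labels())
  if (length(bad) > 0)
    stop("unknown artery label(s): ", paste(bad, collapse = ", "))
  structure(list(data = data, spacing = as.numeric(spacing),
                 labels = labels), class = "vwi_mask")
}

#' @export
print.vwi_mask <- function(x, ...) {
  cat(sprintf("<vwi_mask  %s voxels  %d labels: %s>\n",
              paste(dim(x$data), collapse = "x"), nrow(x$labels),
              paste(paste0(x$labels$artery, "/", substr(x$labels$side, 1, 1)),
                    collapse = " ")))
  invisible(x)
}

# Resolve an artery (+ optional side) to label id(s) in a mask's table.
mask_label_ids <- function(mask, artery, side = NULL) {
  sel <- mask$labels$artery == artery
  if (!is.null(side)) sel <- sel & mask$labels$side == side
  mask$labels$id[sel]
}

# Binary grid for one artery/side (or a set of ids).
mask_binary <- function(mask, artery = NULL, side = NULL, ids = NULL) {
  if (is.null(ids)) ids <- mask_label_ids(mask, artery, side)
  array(mask$data %in% ids, dim = dim(mask$data))
}

#' Create a centerline
#'
#' An ordered polyline in world mm with an artery label and side. Arc length
#' is the cumulative Euclidean length along the points.
#'
#' @param points n x 3 numeric matrix of world-mm coordinates.
#' @param label Artery class (one of [artery_labels()]).
#' @param side `"left"`, `"right"` or `"midline"`.
#' @param bridged Integer vector of point indices that were reconstructed by
#'   path tracing (e.g. across an occlusion) rather than observed.
#' @param flags Optional character vector of status flags
#'   (e.g. `"incomplete"`, `"unrefined-span"`).
#' @return A `vwi_centerline` object with an `arc_length` field (cumulative mm).
#' @export
vwi_centerline <- function(points, label, side = "midline",
                           bridged = integer(0), flags = character(0)) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1) stop("centerline needs at least one point")
  if (nrow(points) > 1) {
    keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > 1e-24)
    bridged <- intersect(bridged, which(keep))
    bridged <- match(bridged, which(keep))
    points <- points[keep, , drop = FALSE]
  }
  structure(list(points = points, label = label, side = side,
                 arc_length = polyline_arclength(points),
                 bridged = bridged, flags = flags),
            class = "vwi_centerline")
}

#' @export
print.vwi_centerline <- function(x, ...) {
  cat(sprintf("<vwi_centerline %s/%s  %d pts  %.1f mm%s%s>\n", x$label, x$side,
              nrow(x$points), centerline_length(x),
              if (length(x$bridged)) sprintf("  %d bridged", length(x$bridged)) else "",
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Total arc length of a centerline (mm)
#' @param line A `vwi_centerline`.
#' @return Numeric scalar, mm.
#' @export
centerline_length <- function(line) {
  if (nrow(line$points) < 2) return(0)
  tail(line$arc_length, 1)
}

# ---------------------------------------------------------------------------
# Polyline helpers (matrices of world-mm points)

polyline_arclength <- function(points) {
  n <- nrow(points)
  if (n < 2) return(rep(0, n))
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Uniform arc-length resampling (linear interpolation); keeps both endpoints.
resample_polyline <- function(points, step) {
  n <- nrow(points)
  if (n < 2) return(points)
  s <- polyline_arclength(points)
  total <- s[n]
  if (total <= 0) return(points[1, , drop = FALSE])
  ns <- max(2L, as.integer(ceiling(total / step)) + 1L)
  at <- seq(0, total, length.out = ns)
  out <- vapply(1:3, function(d) approx(s, points[, d], xout = at,
                                        ties = "ordered")$y, numeric(ns))
  matrix(out, ncol = 3)
}

# Minimum distance from each point in `pts` to the polyline `poly`
# (exact point-to-segment distances).
min_dist_to_polyline <- function(pts, poly) {
  pts <- matrix(pts, ncol = 3)
  m <- nrow(poly)
  if (m == 1) {
    return(sqrt(rowSums(sweep(pts, 2, poly[1, ])^2)))
  }
  a <- poly[-m, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(m - 1)) {
    ap <- sweep(pts, 2, a[s, ])
    t <- pmin(1, pmax(0, (ap %*% ab[s, ]) / len2[s]))
    proj <- cbind(a[s, 1] + t * ab[s, 1], a[s, 2] + t * ab[s, 2],
                  a[s, 3] + t * ab[s, 3])
    d <- sqrt(rowSums((pts - proj)^2))
    best <- pmin(best, d)
  }
  best
}

# World mm -> continuous 0-based voxel coordinates.
world_to_voxel <- function(points, spacing) {
  sweep(matrix(points, ncol = 3), 2, spacing, "/")
}

# 1-based integer voxel indices -> world mm (voxel centres).
voxel_to_world <- function(ijk, spacing) {
  sweep(matrix(ijk, ncol = 3) - 1, 2, spacing, "*")
}

# Nearest-voxel lookup of world points in an array; returns values (0 outside).
lookup_nearest <- function(arr, spacing, points) {
  d <- dim(arr)
  ijk <- round(world_to_voxel(points, spacing)) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  val <- rep(0, nrow(ijk))
  if (any(ok)) val[ok] <- arr[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])]
  val
}

# Standard label table for a set of (artery, side) pairs, ids 1..n in the
# canonical artery order (left before right before midline within an artery).
make_label_table <- function(arteries, sides) {
  ord <- order(match(arteries, artery_labels()),
               match(sides, c("left", "right", "midline")))
  data.frame(id = seq_along(ord), artery = arteries[ord], side = sides[ord],
             stringsAsFactors = FALSE)
}
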