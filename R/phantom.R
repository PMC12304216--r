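# Synthetic multi-sequence vascular phantoms with exact ground truth.
#
# A phantom is a set of tubular branches (smooth curves with per-point radii)
# rasterized into a label mask, rendered into the three MR-VWI sequence kinds
# with their characteristic contrast (TOF: bright lumen / dark background,
# black-blood T1WI and T1WI-CE: dark lumen / mid-grey background), plus the
# exact centerlines the geometry pipeline should recover. Occluded spans are
# invisible on TOF (lumen falls to background level) but keep a distinct
# wall-like signal on the black-blood sequences, mirroring how fresh thrombus
# and enhancing walls keep occluded segments traceable clinically.

#' Define a phantom branch
#'
#' @param label Artery class, one of [artery_labels()].
#' @param side `"left"`, `"right"` or `"midline"`.
#' @param control_points n x 3 matrix (n >= 2) of world-mm points; a natural
#'   cubic spline is interpolated through them.
#' @param radius_mm Lumen radius in mm: scalar or one value per control point
#'   (linearly interpolated along arc length).
#' @param occlusion_span Optional `c(lo, hi)` arc-length interval (mm) where
#'   the lumen is occluded.
#' @return A `vwi_branch` object.
#' @export
vwi_branch <- function(label, side, control_points, radius_mm,
                       occlusion_span = NULL) {
  if (!label %in% artery_labels())
    stop("unknown artery label: ", label)
  control_points <- matrix(as.numeric(control_points), ncol = 3)
  if (nrow(control_points) < 2) stop("branch needs >= 2 control points")
  radius_mm <- as.numeric(radius_mm)
  if (!length(radius_mm) %in% c(1L, nrow(control_points)))
    stop("radius_mm must be scalar or one per control point")
  if (any(radius_mm <= 0)) stop("radii must be positive")
  structure(list(label = label, side = side,
                 control_points = control_points, radius_mm = radius_mm,
                 occlusion_span = occlusion_span), class = "vwi_branch")
}

#' Define a phantom specification
#'
#' Defaults encode a typical small-FOV head-and-neck VWI acquisition:
#' 0.6 mm isotropic voxels and sequence mean intensities giving bright-lumen
#' TOF contrast and dark-lumen black-blood contrast.
#'
#' @param grid_shape Voxel counts per axis (all >= 16).
#' @param spacing_mm Per-axis voxel size in mm.
#' @param branches List of [vwi_branch()] objects.
#' @param noise_sigma Additive Gaussian noise scale, named per sequence kind
#'   or a single value for all.
#' @param background_level,lumen_level,wall_level Named per-sequence mean
#'   intensities; `wall_level` is the signal of occluded lumen on black-blood
#'   sequences.
#' @param seed Integer RNG seed; with the spec it fully determines the sample.
#' @return A `vwi_phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(0.6, 0.6, 0.6),
                         branches = list(),
                         noise_sigma = 5,
                         background_level = c("T1WI" = 120, "T1WI-CE" = 110, "TOF" = 60),
                         lumen_level = c("T1WI" = 40, "T1WI-CE" = 35, "TOF" = 220),
                         wall_level = c("T1WI" = 185, "T1WI-CE" = 195, "TOF" = 60),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 16))
    stop("grid_shape must be 3 values, all >= 16")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  kinds <- sequence_kinds()
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x))) x <- rep(x, 3)
    if (is.null(names(x))) names(x) <- kinds
    x[kinds]
  }
  noise_sigma <- expand(noise_sigma)
  if (any(noise_sigma < 0)) stop("noise_sigma must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 branches = branches, noise_sigma = noise_sigma,
                 background_level = expand(background_level),
                 lumen_level = expand(lumen_level),
                 wall_level = expand(wall_level),
                 seed = as.integer(seed)),
            class = "vwi_phantom_spec")
}

# Natural cubic spline through control points, chord-length parameterised,
# resampled at uniform arc-length step. Returns points, per-point radius and
# cumulative arc length.
branch_curve <- function(branch, step) {
  cp <- branch$control_points
  n <- nrow(cp)
  tpar <- polyline_arclength(cp)
  if (tail(tpar, 1) <= 0) stop("degenerate branch control polygon")
  tfine <- seq(0, tail(tpar, 1), length.out = max(200L, 20L * n))
  pts <- if (n == 2) {
    vapply(1:3, function(d) approx(tpar, cp[, d], xout = tfine)$y,
           numeric(length(tfine)))
  } else {
    vapply(1:3, function(d) spline(tpar, cp[, d], xout = tfine,
                                   method = "natural")$y,
           numeric(length(tfine)))
  }
  pts <- matrix(pts, ncol = 3)
  pts <- resample_polyline(pts, step)
  s <- polyline_arclength(pts)
  rad <- if (length(branch$radius_mm) == 1) rep(branch$radius_mm, nrow(pts)) else {
    # control-point radii interpolated by normalised arc fraction
    approx(tpar / tail(tpar, 1), branch$radius_mm,
           xout = s / tail(s, 1))$y
  }
  list(points = pts, radius = rad, arc = s)
}

#' Generate a synthetic phantom sample
#'
#' Rasterizes each branch (voxels within the local radius of the smooth
#' curve), renders the three sequence volumes with additive Gaussian noise,
#' and returns exact ground-truth centerlines. Identical spec (including
#' seed) gives bit-identical output.
#'
#' Overlap between branches of different artery/side is an error except
#' within `junction_mm` of either branch's ends, where parent/child vessels
#' legitimately meet; there the geometrically closer branch claims the voxel.
#'
#' @param spec A [phantom_spec()].
#' @param junction_mm Arc-length window at branch ends where overlap with
#'   another branch is treated as an anatomical junction (default 6 mm).
#' @return A `vwi_phantom` sample: `volumes` (named [vwi_volume] list),
#'   `mask` ([vwi_mask]), `centerlines` (list of [vwi_centerline]), plus the
#'   generating `spec` and internal per-voxel branch/arc grids used by the
#'   augmentation ops.
#' @export
generate_phantom <- function(spec, junction_mm = 6) {
  stopifnot(inherits(spec, "vwi_phantom_spec"))
  if (length(spec$branches) == 0) stop("spec has no branches")
  dm <- spec$grid_shape
  sp <- spec$spacing_mm
  step <- 0.25 * min(sp)
  extent <- (dm - 1) * sp

  nb <- length(spec$branches)
  b_art <- vapply(spec$branches, `[[`, "", "label")
  b_side <- vapply(spec$branches, `[[`, "", "side")
  key <- paste(b_art, b_side)

  dist <- array(Inf, dm)
  bidx <- array(0L, dm)
  arc <- array(NA_real_, dm)

  curves <- vector("list", nb)
  for (b in seq_len(nb)) {
    br <- spec$branches[[b]]
    cv <- branch_curve(br, step)
    curves[[b]] <- cv
    total <- tail(cv$arc, 1)
    if (!is.null(br$occlusion_span)) {
      os <- br$occlusion_span
      if (length(os) != 2 || os[1] < 0 || os[2] > total + 1e-9 || os[1] >= os[2])
        stop(sprintf("branch %s/%s: occlusion_span outside [0, %.2f] mm",
                     br$label, br$side, total))
    }
    lo <- sweep(cv$points, 1, cv$radius, "-")
    hi <- sweep(cv$points, 1, cv$radius, "+")
    if (any(lo < -1e-9) || any(sweep(hi, 2, extent) > 1e-9))
      stop(sprintf("branch %s/%s exits the grid", br$label, br$side))

    for (s in seq_len(nrow(cv$points))) {
      p <- cv$points[s, ]
      r <- cv$radius[s]
      i0 <- pmax(1L, floor(p / sp - r / sp) + 1L - 1L)
      i1 <- pmin(dm, ceiling(p / sp + r / sp) + 1L + 1L)
      xs <- (i0[1]:i1[1] - 1) * sp[1] - p[1]
      ys <- (i0[2]:i1[2] - 1) * sp[2] - p[2]
      zs <- (i0[3]:i1[3] - 1) * sp[3] - p[3]
      d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
      sel <- which(d2 <= r * r)
      if (length(sel) == 0) next
      nxb <- length(xs); nyb <- length(ys)
      s0 <- sel - 1L
      ii <- i0[1] + s0 %% nxb
      jj <- i0[2] + (s0 %/% nxb) %% nyb
      kk <- i0[3] + s0 %/% (nxb * nyb)
      lin <- ii + dm[1] * (jj - 1 + dm[2] * (kk - 1))
      nd <- sqrt(d2[sel])

      cur <- bidx[lin]
      other <- cur != 0L & cur != b
      clash <- other
      clash[other] <- key[cur[other]] != key[b]
      if (any(clash)) {
        # tolerate junction contact near either branch's ends
        arcA <- arc[lin[clash]]
        lenA <- vapply(cur[clash], function(bb) tail(curves[[bb]]$arc, 1), 0)
        nearA <- arcA <= junction_mm | arcA >= lenA - junction_mm
        nearB <- cv$arc[s] <= junction_mm | cv$arc[s] >= total - junction_mm
        if (any(!nearA & !nearB))
          stop(sprintf("branches %s and %s overlap away from their junctions",
                       key[unique(cur[clash])][1], key[b]))
      }
      upd <- nd < dist[lin]
      if (any(upd)) {
        lu <- lin[upd]
        dist[lu] <- nd[upd]
        bidx[lu] <- b
        arc[lu] <- cv$arc[s]
      }
    }
  }

  # label table over the distinct (artery, side) pairs present
  uk <- !duplicated(key)
  labels <- make_label_table(b_art[uk], b_side[uk])
  id_of_branch <- labels$id[match(key, paste(labels$artery, labels$side))]
  maskdat <- array(0L, dm)
  inmask <- bidx > 0L
  maskdat[inmask] <- id_of_branch[bidx[inmask]]
  mask <- vwi_mask(maskdat, sp, labels)

  # sequence volumes
  kinds <- sequence_kinds()
  occl <- array(FALSE, dm) # occluded lumen voxels
  for (b in seq_len(nb)) {
    os <- spec$branches[[b]]$occlusion_span
    if (is.null(os)) next
    occl <- occl | (bidx == b & !is.na(arc) & arc >= os[1] & arc <= os[2])
  }
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  volumes <- list()
  for (kd in kinds) {
    v <- array(spec$background_level[[kd]], dm)
    v[inmask] <- spec$lumen_level[[kd]]
    if (any(occl)) {
      v[occl] <- if (kd == "TOF") spec$background_level[[kd]] else
        spec$wall_level[[kd]]
    }
    if (spec$noise_sigma[[kd]] > 0)
      v <- v + array(rnorm(prod(dm), sd = spec$noise_sigma[[kd]]), dm)
    volumes[[kd]] <- vwi_volume(v, sp, kind = kd)
  }
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())

  centerlines <- lapply(seq_len(nb), function(b)
    vwi_centerline(curves[[b]]$points, b_art[b], b_side[b]))

  structure(list(volumes = volumes, mask = mask, centerlines = centerlines,
                 spec = spec, branch_idx = bidx, branch_arc = arc),
            class = "vwi_phantom")
}

#' @export
print.vwi_phantom <- function(x, ...) {
  cat(sprintf("<vwi_phantom  %s voxels  %d branches  %d sequences>\n",
              paste(dim(x$mask$data), collapse = "x"),
              length(x$centerlines), length(x$volumes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Scene builders: the canonical study conditions used by tests and examples.
# Grid 64^3 at 0.6 mm isotropic; carotid-calibre radii (CCA ~3 mm,
# ICA ~2.2 mm, ECA ~1.8 mm); mild seeded jitter in position and radius.

with_seed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  expr
}

#' Single-tube phantom spec
#'
#' One gently curved ICA-like tube spanning the grid in z, optionally with an
#' occluded middle span (invisible on TOF, wall signal on black-blood).
#'
#' @param seed Integer seed (drives jitter and the rendered noise).
#' @param occluded Add an occlusion over the middle third of the vessel?
#' @param grid_shape,spacing_mm Grid geometry.
#' @param noise_sigma Noise scale (see [phantom_spec()]).
#' @return A [phantom_spec()].
#' @export
spec_single_tube <- function(seed = 1L, occluded = FALSE,
                             grid_shape = c(64, 64, 64),
                             spacing_mm = c(0.6, 0.6, 0.6),
                             noise_sigma = 5) {
  with_seed(seed, {
    ext <- (grid_shape - 1) * spacing_mm
    cx <- ext[1] * runif(1, 0.4, 0.6)
    cy <- ext[2] * runif(1, 0.4, 0.6)
    amp <- runif(1, 1, 3)
    ph <- runif(1, 0, 2 * pi)
    z <- seq(0.12, 0.88, length.out = 7) * ext[3]
    cp <- cbind(cx + amp * sin(ph + seq(0, pi, length.out = 7)),
                cy + amp * cos(ph + seq(0, 0.8 * pi, length.out = 7)) * 0.5,
                z)
    r <- 2.2 * runif(1, 0.9, 1.1)
    span <- NULL
    if (occluded) {
      # occlusion over the middle third of the arc
      len <- tail(polyline_arclength(cp), 1)
      span <- c(len / 3, 2 * len / 3)
    }
    phantom_spec(grid_shape, spacing_mm,
                 branches = list(vwi_branch("ICA", "left", cp, r,
                                            occlusion_span = span)),
                 noise_sigma = noise_sigma, seed = seed)
  })
}

#' Y-bifurcation phantom spec
#'
#' A CCA-like trunk splitting into ICA- and ECA-like daughters on one side,
#' the classic carotid bifurcation geometry.
#'
#' @inheritParams spec_single_tube
#' @param side Which side the vessel tree sits on.
#' @return A [phantom_spec()].
#' @export
spec_bifurcation <- function(seed = 1L, side = "left",
                             grid_shape = c(64, 64, 64),
                             spacing_mm = c(0.6, 0.6, 0.6),
                             noise_sigma = 5) {
  with_seed(seed, {
    ext <- (grid_shape - 1) * spacing_mm
    sgn <- if (side == "left") 1 else -1
    cx <- ext[1] * (0.5 + sgn * runif(1, 0.11, 0.17))
    cy <- ext[2] * runif(1, 0.45, 0.55)
    zb <- ext[3] * runif(1, 0.42, 0.52) # bifurcation height
    jit <- function(s) runif(1, -s, s) # bounded so margins hold for any seed
    cca <- cbind(cx + c(jit(0.5), jit(0.5), 0),
                 cy + c(jit(0.5), jit(0.5), 0),
                 c(0.10 * ext[3], 0.30 * ext[3], zb))
    ica <- cbind(cx + c(0, sgn * 2.6, sgn * 3.8) + c(0, jit(0.3), jit(0.3)),
                 cy + c(0, 2.0, 2.8) + c(0, jit(0.3), jit(0.3)),
                 c(zb, 0.62 * ext[3], 0.88 * ext[3]))
    eca <- cbind(cx + c(0, sgn * 0.5, sgn * 1.0) + c(0, jit(0.3), jit(0.3)),
                 cy - c(0, 3.0, 4.0) + c(0, jit(0.3), jit(0.3)),
                 c(zb, 0.62 * ext[3], 0.86 * ext[3]))
    phantom_spec(grid_shape, spacing_mm,
                 branches = list(
                   vwi_branch("CCA", side, cca, 3.0 * runif(1, 0.95, 1.05)),
                   vwi_branch("ICA", side, ica, 2.2 * runif(1, 0.95, 1.05)),
                   vwi_branch("ECA", side, eca, 1.8 * runif(1, 0.95, 1.05))),
                 noise_sigma = noise_sigma, seed = seed)
  })
}

#' Bilateral head-neck phantom spec
#'
#' Left and right carotid bifurcations (CCA, ICA, ECA on each side) with
#' approximate left/right symmetry and seeded jitter; the training scene for
#' the segmentation-and-recognition network.
#'
#' @inheritParams spec_single_tube
#' @param occluded_prob Probability that one branch receives a simulated
#'   occlusion.
#' @return A [phantom_spec()].
#' @export
spec_head_neck <- function(seed = 1L, occluded_prob = 0.3,
                           grid_shape = c(64, 64, 64),
                           spacing_mm = c(0.6, 0.6, 0.6),
                           noise_sigma = 5) {
  sl <- spec_bifurcation(seed, "left", grid_shape, spacing_mm, noise_sigma)
  sr <- spec_bifurcation(seed + 500013L, "right", grid_shape, spacing_mm,
                         noise_sigma)
  branches <- c(sl$branches, sr$branches)
  with_seed(seed + 7L, {
    if (runif(1) < occluded_prob) {
      b <- sample(length(branches), 1)
      cv <- branch_curve(branches[[b]], 0.25 * min(spacing_mm))
      len <- tail(cv$arc, 1)
      olen <- runif(1, 4, min(10, len / 3))
      lo <- runif(1, 0.25 * len, 0.75 * len - olen)
      branches[[b]]$occlusion_span <- c(lo, lo + olen)
    }
    phantom_spec(grid_shape, spacing_mm, branches = branches,
                 noise_sigma = noise_sigma, seed = seed)
  })
}
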