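# Training-set augmentation: displacement, truncation, left-right reversal
# and simulated occlusion, applied as paired transforms of volumes, mask and
# ground-truth centerlines. The default configuration expands each sample
# six-fold: the original, one of each of the four operations, and one
# displacement-then-flip composition.

#' Augmentation configuration
#'
#' @param displacement,truncation,flip,occlusion Enable the four operations.
#' @param compose_displacement_flip Add a composed displacement + left-right
#'   reversal sample (the sixth sample of the default six-fold expansion).
#' @param max_shift_vox Maximum per-axis displacement magnitude (voxels).
#' @param crop_frac Truncation window size as a fraction of each axis.
#' @param occl_len_mm Range of simulated occlusion lengths (mm).
#' @param seed Integer seed; `NULL` derives one from the sample's own seed so
#'   augmentation stays a pure function of (sample, config).
#' @return An `augment_config` list.
#' @export
augment_config <- function(displacement = TRUE, truncation = TRUE,
                           flip = TRUE, occlusion = TRUE,
                           compose_displacement_flip = TRUE,
                           max_shift_vox = 6L, crop_frac = 0.75,
                           occl_len_mm = c(4, 10), seed = NULL) {
  structure(list(displacement = displacement, truncation = truncation,
                 flip = flip, occlusion = occlusion,
                 compose_displacement_flip = compose_displacement_flip,
                 max_shift_vox = as.integer(max_shift_vox),
                 crop_frac = crop_frac, occl_len_mm = occl_len_mm,
                 seed = seed), class = "augment_config")
}

#' Augment a phantom sample
#'
#' @param sample A `vwi_phantom` sample.
#' @param config An [augment_config()].
#' @return List of `vwi_phantom` samples; with the default config, exactly 6
#'   per input (original + displacement + truncation + left-right reversal +
#'   simulated occlusion + displacement-then-flip).
#' @export
augment_phantom <- function(sample, config = augment_config()) {
  stopifnot(inherits(sample, "vwi_phantom"))
  seed <- if (is.null(config$seed)) sample$spec$seed + 104729L else config$seed
  with_seed(seed, {
    out <- list(sample)
    shift <- NULL
    if (config$displacement) {
      shift <- draw_shift(config$max_shift_vox)
      out <- c(out, list(translate_sample(sample, shift)))
    }
    if (config$truncation)
      out <- c(out, list(truncate_sample(sample, config$crop_frac)))
    if (config$flip)
      out <- c(out, list(flip_sample(sample)))
    if (config$occlusion)
      out <- c(out, list(occlude_sample(sample, config$occl_len_mm)))
    if (config$compose_displacement_flip) {
      if (is.null(shift)) shift <- draw_shift(config$max_shift_vox)
      out <- c(out, list(flip_sample(translate_sample(sample, shift))))
    }
    out
  })
}

draw_shift <- function(maxv) {
  s <- sample(seq(-maxv, maxv), 3, replace = TRUE)
  if (all(s == 0)) s[1] <- maxv
  s
}

shift_array <- function(a, shift, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Translate a phantom sample by integer voxels
#'
#' Volumes are padded with their sequence background level, the mask with
#' background; centerline world coordinates shift by `shift * spacing` mm.
#'
#' @param sample A `vwi_phantom`.
#' @param shift Integer voxel shift, length 3.
#' @return Translated `vwi_phantom`.
#' @export
translate_sample <- function(sample, shift) {
  shift <- as.integer(shift)
  sp <- sample$mask$spacing
  vols <- lapply(sample$volumes, function(v) {
    bg <- sample$spec$background_level[[v$kind]]
    vwi_volume(shift_array(v$data, shift, bg), sp, v$kind)
  })
  mask <- vwi_mask(shift_array(sample$mask$data, shift, 0L), sp,
                   sample$mask$labels)
  dmm <- shift * sp
  cls <- lapply(sample$centerlines, function(cl)
    vwi_centerline(sweep(cl$points, 2, dmm, "+"), cl$label, cl$side,
                   bridged = cl$bridged, flags = cl$flags))
  structure(list(volumes = vols, mask = mask, centerlines = cls,
                 spec = sample$spec,
                 branch_idx = shift_array(sample$branch_idx, shift, 0L),
                 branch_arc = shift_array(sample$branch_arc, shift, NA_real_)),
            class = "vwi_phantom")
}

#' Truncate a phantom sample to a random sub-window
#'
#' Emulates a reduced field of view. The window is redrawn (with a warning)
#' if it contains no vessel voxels; centerline points outside the window are
#' dropped and coordinates re-expressed in the cropped frame.
#'
#' @param sample A `vwi_phantom`.
#' @param crop_frac Window size as a fraction of each axis, or an explicit
#'   window `list(lo =, hi =)` of 1-based inclusive indices.
#' @return Truncated `vwi_phantom`.
#' @export
truncate_sample <- function(sample, crop_frac = 0.75) {
  d <- dim(sample$mask$data)
  if (is.list(crop_frac)) {
    lo <- crop_frac$lo; hi <- crop_frac$hi
  } else {
    sz <- pmax(16L, as.integer(ceiling(d * crop_frac)))
    for (try in 1:25) {
      lo <- vapply(1:3, function(ax) sample.int(d[ax] - sz[ax] + 1L, 1), 1L)
      hi <- lo + sz - 1L
      if (any(sample$mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] > 0))
        break
      if (try == 1) warning("truncation window empty of vessel; redrawing")
    }
  }
  crop <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sp <- sample$mask$spacing
  vols <- lapply(sample$volumes, function(v) vwi_volume(crop(v$data), sp, v$kind))
  mask <- vwi_mask(crop(sample$mask$data), sp, sample$mask$labels)
  orig <- (lo - 1) * sp
  ext <- (hi - lo) * sp
  cls <- list()
  for (cl in sample$centerlines) {
    p <- sweep(cl$points, 2, orig, "-")
    keep <- p[, 1] >= -1e-9 & p[, 2] >= -1e-9 & p[, 3] >= -1e-9 &
      p[, 1] <= ext[1] + 1e-9 & p[, 2] <= ext[2] + 1e-9 & p[, 3] <= ext[3] + 1e-9
    if (sum(keep) >= 1)
      cls <- c(cls, list(vwi_centerline(p[keep, , drop = FALSE], cl$label,
                                        cl$side, flags = cl$flags)))
  }
  newspec <- sample$spec
  newspec$grid_shape <- dim(mask$data)
  structure(list(volumes = vols, mask = mask, centerlines = cls,
                 spec = newspec,
                 branch_idx = crop(sample$branch_idx),
                 branch_arc = crop(sample$branch_arc)),
            class = "vwi_phantom")
}

flip_side <- function(side) {
  c(left = "right", right = "left", midline = "midline")[[side]]
}

#' Left-right reversal of a phantom sample
#'
#' Mirrors all grids across the mid-sagittal plane (x axis), swaps left/right
#' in the label table, centerlines and spec. Applying it twice restores the
#' sample exactly.
#'
#' @param sample A `vwi_phantom`.
#' @return Mirrored `vwi_phantom`.
#' @export
flip_sample <- function(sample) {
  d <- dim(sample$mask$data)
  sp <- sample$mask$spacing
  fl <- function(a) a[d[1]:1, , , drop = FALSE]
  vols <- lapply(sample$volumes, function(v) vwi_volume(fl(v$data), sp, v$kind))
  labels <- sample$mask$labels
  labels$side <- vapply(labels$side, flip_side, "")
  mask <- vwi_mask(fl(sample$mask$data), sp, labels)
  xmax <- (d[1] - 1) * sp[1]
  cls <- lapply(sample$centerlines, function(cl) {
    p <- cl$points
    p[, 1] <- xmax - p[, 1]
    vwi_centerline(p, cl$label, flip_side(cl$side), bridged = cl$bridged,
                   flags = cl$flags)
  })
  newspec <- sample$spec
  newspec$branches <- lapply(newspec$branches, function(br) {
    br$control_points[, 1] <- xmax - br$control_points[, 1]
    br$side <- flip_side(br$side)
    br
  })
  structure(list(volumes = vols, mask = mask, centerlines = cls,
                 spec = newspec,
                 branch_idx = fl(sample$branch_idx),
                 branch_arc = fl(sample$branch_arc)),
            class = "vwi_phantom")
}

#' Simulate an occlusion in a phantom sample
#'
#' Picks one branch and an arc-length span and rewrites the sequence
#' intensities there: TOF lumen signal falls to background (the occluded
#' segment disappears from the angiogram) while the black-blood sequences
#' take a wall-like signal so the segment stays traceable. The mask and
#' centerlines are unchanged (the vessel still exists).
#'
#' @param sample A `vwi_phantom`.
#' @param occl_len_mm Length range (mm) to draw from.
#' @param branch Optional branch index; default random.
#' @param span Optional explicit `c(lo, hi)` arc span (mm).
#' @return `vwi_phantom` with modified volumes.
#' @export
occlude_sample <- function(sample, occl_len_mm = c(4, 10), branch = NULL,
                           span = NULL) {
  nb <- max(sample$branch_idx)
  if (is.null(branch)) branch <- sample.int(nb, 1)
  arcs <- sample$branch_arc[sample$branch_idx == branch]
  if (length(arcs) == 0) return(sample)
  lo_a <- min(arcs, na.rm = TRUE); hi_a <- max(arcs, na.rm = TRUE)
  if (is.null(span)) {
    len <- runif(1, occl_len_mm[1], min(occl_len_mm[2],
                                        max(occl_len_mm[1], (hi_a - lo_a) / 2)))
    start <- runif(1, lo_a + 0.15 * (hi_a - lo_a),
                   max(lo_a + 0.15 * (hi_a - lo_a),
                       hi_a - 0.15 * (hi_a - lo_a) - len))
    span <- c(start, start + len)
  }
  sel <- sample$branch_idx == branch & !is.na(sample$branch_arc) &
    sample$branch_arc >= span[1] & sample$branch_arc <= span[2]
  if (!any(sel)) return(sample)
  spc <- sample$spec
  vols <- sample$volumes
  for (kd in names(vols)) {
    lvl <- if (kd == "TOF") spc$background_level[[kd]] else spc$wall_level[[kd]]
    noise <- if (spc$noise_sigma[[kd]] > 0)
      rnorm(sum(sel), sd = spc$noise_sigma[[kd]]) else 0
    vols[[kd]]$data[sel] <- lvl + noise
  }
  out <- sample
  out$volumes <- vols
  out
}
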