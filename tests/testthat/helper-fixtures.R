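# Shared fixtures, built in code.

# Flat-ended discrete cylinder mask along z (axis through voxel centres).
flat_cylinder_mask <- function(r_vox = 3, len_vox = 40, dims = c(24, 24, 48),
                               spacing = c(1, 1, 1), centre = c(12, 12),
                               z0 = 5, label = "ICA", side = "left") {
  arr <- array(0L, dims)
  for (k in z0:(z0 + len_vox - 1))
    for (i in 1:dims[1]) for (j in 1:dims[2])
      if ((i - centre[1])^2 + (j - centre[2])^2 <= r_vox^2) arr[i, j, k] <- 1L
  vwi_mask(arr, spacing, data.frame(id = 1L, artery = label, side = side,
                                    stringsAsFactors = FALSE))
}

# Y-shaped tube mask: trunk splitting into two straight daughters.
y_tube_mask <- function(dims = c(40, 24, 48), spacing = c(1, 1, 1)) {
  arr <- array(0L, dims)
  mark <- function(p0, p1, r) {
    n <- ceiling(sqrt(sum((p1 - p0)^2)) * 4)
    for (t in seq(0, 1, length.out = n)) {
      p <- p0 + t * (p1 - p0)
      lo <- pmax(1, floor(p - r)); hi <- pmin(dims, ceiling(p + r))
      for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3])
        if (sum((c(i, j, k) - p)^2) <= r^2) arr[i, j, k] <<- 1L
    }
  }
  mark(c(20, 12, 4), c(20, 12, 24), 3)
  mark(c(20, 12, 24), c(10, 12, 44), 2.6)
  mark(c(20, 12, 24), c(30, 12, 44), 2.6)
  vwi_mask(arr, spacing, data.frame(id = 1L, artery = "CCA", side = "left",
                                    stringsAsFactors = FALSE))
}

# Straight-tube phantom with the axis through voxel centres (noiseless by
# default so appearance checks are exact).
straight_tube_spec <- function(seed = 1, noise = 0, occlusion_span = NULL) {
  phantom_spec(
    grid_shape = c(64, 64, 64), spacing_mm = c(0.6, 0.6, 0.6),
    branches = list(vwi_branch("ICA", "left",
                               rbind(c(19.8, 19.8, 2), c(19.8, 19.8, 36)),
                               1.8, occlusion_span = occlusion_span)),
    noise_sigma = noise, seed = seed)
}

# Remove an arc-length span of a branch from the mask (what a TOF-only
# segmentation would miss across an occlusion).
gap_mask <- function(sample, branch = 1, span) {
  gapped <- sample$mask
  sel <- sample$branch_idx == branch & !is.na(sample$branch_arc) &
    sample$branch_arc >= span[1] & sample$branch_arc <= span[2]
  gapped$data[sel] <- 0L
  gapped
}

# Truth-mask-driven geometry pipeline (bypasses the network).
recover_centerlines <- function(mask, field = distance_field(mask),
                                prune_len = 3, max_bridge = 10) {
  lines <- list()
  for (a in unique(mask$labels$artery))
    lines <- c(lines, principal_centerlines(skeletonize(mask, a),
                                            prune_len = prune_len))
  lines <- connect_and_extend(lines, field, max_bridge = max_bridge,
                              mask = mask)
  lapply(lines, refine_with_lumen, lumen = mask)
}

# Exhaustive nearest-neighbour MCD oracle (double loop).
mcd_oracle <- function(a, b) {
  da <- apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
  db <- apply(b, 1, function(p) min(sqrt(colSums((t(a) - p)^2))))
  0.5 * (mean(da) + mean(db))
}

# igraph shortest-path oracle for the distance-field path cost.
trace_cost_oracle <- function(field, start_ijk, end_ijk, eps = 0.1) {
  dm <- dim(field$data); sp <- field$spacing
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx <- arrayInd(seq_len(prod(dm)), dm)
  ed <- NULL; wt <- NULL
  for (r in seq_len(26)) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    to <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1 + dm[2] * (nb[ok, 3] - 1))
    len <- sqrt(sum((offs[r, ] * sp)^2))
    ed <- rbind(ed, cbind(which(ok), to))
    wt <- c(wt, len / (field$data[to] + eps))
  }
  g <- igraph::graph_from_edgelist(ed, directed = TRUE)
  igraph::E(g)$weight <- wt
  s <- start_ijk[1] + dm[1] * (start_ijk[2] - 1 + dm[2] * (start_ijk[3] - 1))
  e <- end_ijk[1] + dm[1] * (end_ijk[2] - 1 + dm[2] * (end_ijk[3] - 1))
  igraph::distances(g, v = s, to = e, mode = "out")[1, 1]
}
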