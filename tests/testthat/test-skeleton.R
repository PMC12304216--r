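cyl <- flat_cylinder_mask(r_vox = 4, len_vox = 36, dims = c(24, 24, 44),
                          z0 = 5)

test_that("cylinder skeleton is a subset of the mask and hugs the axis", {
  sk <- skeletonize(cyl, "ICA")
  expect_gt(nrow(sk$nodes), 10)
  # subset invariant
  expect_true(all(cyl$data[sk$nodes] > 0))
  # all nodes within 1 voxel of the true axis (x = 12, y = 12)
  d_axis <- sqrt((sk$nodes[, 1] - 12)^2 + (sk$nodes[, 2] - 12)^2)
  expect_lte(max(d_axis), 1 + 1e-9)
})

test_that("straight tube yields one centerline with near-true arc length", {
  # round-capped tube: the medial curve runs between the cap centres, so the
  # true length is the generating curve's 34 mm
  ph <- generate_phantom(straight_tube_spec())
  cls <- principal_centerlines(skeletonize(ph$mask, "ICA"))
  expect_length(cls, 1)
  expect_identical(cls[[1]]$label, "ICA")
  expect_lt(abs(centerline_length(cls[[1]]) - 34) / 34, 0.05)
  # ordered inferior -> superior
  expect_lt(cls[[1]]$points[1, 3], cls[[1]]$points[nrow(cls[[1]]$points), 3])
  expect_equal(cls[[1]]$arc_length,
               polyline_arclength(cls[[1]]$points))
})

test_that("empty label yields an empty skeleton and no centerlines", {
  sk <- skeletonize(cyl, "MCA")
  expect_identical(nrow(sk$nodes), 0L)
  expect_length(principal_centerlines(sk), 0)
})

test_that("Y-junction skeleton has exactly one degree-3 node after pruning", {
  ym <- y_tube_mask()
  sk <- skeletonize(ym, "CCA")
  cls <- principal_centerlines(sk, prune_len = 4)
  expect_length(cls, 3) # trunk + two daughters
  # brute-force degree census on the pruned path graph: endpoints shared by
  # the three paths meet at exactly one junction point
  ends <- do.call(rbind, lapply(cls, function(cl)
    rbind(cl$points[1, ], cl$points[nrow(cl$points), ])))
  key <- apply(round(ends, 6), 1, paste, collapse = ",")
  expect_identical(sort(table(key), decreasing = TRUE)[[1]], 3L)
  expect_identical(sum(table(key) == 3L), 1L)
})

test_that("two disjoint same-label tubes get sides from the mid-sagittal plane", {
  dims <- c(40, 20, 40)
  arr <- array(0L, dims)
  for (k in 4:36) {
    for (i in 1:dims[1]) for (j in 1:dims[2]) {
      if ((i - 30)^2 + (j - 10)^2 <= 9) arr[i, j, k] <- 1L # high x: left
      if ((i - 8)^2 + (j - 10)^2 <= 9) arr[i, j, k] <- 2L  # low x: right
    }
  }
  m <- vwi_mask(arr, c(1, 1, 1),
                data.frame(id = 1:2, artery = "ICA",
                           side = c("left", "right"), stringsAsFactors = FALSE))
  cls <- principal_centerlines(skeletonize(m, "ICA"))
  expect_length(cls, 2)
  sides <- vapply(cls, `[[`, "", "side")
  mean_x <- vapply(cls, function(cl) mean(cl$points[, 1]), 0)
  expect_identical(sides[order(-mean_x)], c("left", "right"))
})

test_that("a cyclic skeleton component is broken with a warning", {
  # solid torus-like square ring: genuinely cyclic topology
  dims <- c(30, 30, 12)
  arr <- array(0L, dims)
  for (i in 1:30) for (j in 1:30) {
    on_ring <- (abs(i - 15) > 6 | abs(j - 15) > 6) &
      abs(i - 15) < 11 & abs(j - 15) < 11
    if (on_ring) arr[i, j, 5:8] <- 1L
  }
  m <- vwi_mask(arr, c(1, 1, 1), data.frame(id = 1L, artery = "BA",
                                            side = "midline",
                                            stringsAsFactors = FALSE))
  expect_warning(cls <- principal_centerlines(skeletonize(m, "BA")), "cycl")
  expect_gt(length(cls), 0)
})
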