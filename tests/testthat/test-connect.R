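test_that("an occlusion gap is bridged through the black-blood field", {
  ph <- generate_phantom(spec_single_tube(21))
  len <- centerline_length(ph$centerlines[[1]])
  gapped <- gap_mask(ph, 1, c(len / 2 - 3, len / 2 + 3)) # 6 mm gap
  field_bb <- distance_field(ph$mask) # black-blood still sees the occluded wall
  lines <- principal_centerlines(skeletonize(gapped, "ICA"))
  expect_gte(length(lines), 2)
  merged <- connect_and_extend(lines, field_bb)
  expect_length(merged, 1)
  expect_gt(length(merged[[1]]$bridged), 0)
  expect_false("incomplete" %in% merged[[1]]$flags)
  # the bridged span lies within the 2-voxel-dilated true lumen
  dil <- vwikit:::cpp_dilate26(array(ph$mask$data > 0, dim(ph$mask$data)),
                               dim(ph$mask$data), 2L)
  br <- merged[[1]]$points[merged[[1]]$bridged, , drop = FALSE]
  expect_true(all(vwikit:::lookup_nearest(dil, ph$mask$spacing, br) > 0))
  # and the reconnected line recovers the truth geometry
  ref <- refine_with_lumen(merged[[1]], ph$mask)
  expect_lt(mcd(ph$centerlines[[1]], ref), max(ph$mask$spacing))
})

test_that("gap-free input passes through nearly unchanged", {
  cyl <- flat_cylinder_mask(r_vox = 3, len_vox = 30, dims = c(20, 20, 40),
                            z0 = 5)
  lines <- principal_centerlines(skeletonize(cyl, "ICA"))
  out <- connect_and_extend(lines, distance_field(cyl))
  expect_length(out, length(lines))
  expect_lt(mcd(lines[[1]], out[[1]]), 0.75) # resampling/extension tolerance
  expect_identical(out[[1]]$label, lines[[1]]$label)
  expect_identical(out[[1]]$side, lines[[1]]$side)
})

test_that("gaps beyond max_bridge stay separate and are flagged incomplete", {
  ph <- generate_phantom(spec_single_tube(22))
  len <- centerline_length(ph$centerlines[[1]])
  gapped <- gap_mask(ph, 1, c(len / 2 - 6, len / 2 + 6)) # 12 mm gap
  lines <- principal_centerlines(skeletonize(gapped, "ICA"))
  out <- connect_and_extend(lines, distance_field(ph$mask), max_bridge = 6)
  expect_gte(length(out), 2)
  expect_true(all(vapply(out, function(l) "incomplete" %in% l$flags, TRUE)))
})

test_that("no operation changes a centerline's label or side", {
  ph <- generate_phantom(spec_bifurcation(13))
  lines <- list()
  for (a in unique(ph$mask$labels$artery))
    lines <- c(lines, principal_centerlines(skeletonize(ph$mask, a)))
  before <- vapply(lines, function(l) paste(l$label, l$side), "")
  out <- connect_and_extend(lines, distance_field(ph$mask))
  out <- lapply(out, refine_with_lumen, lumen = ph$mask)
  after <- vapply(out, function(l) paste(l$label, l$side), "")
  expect_setequal(after, before)
})

test_that("lumen refinement recenters offset lines and respects its guards", {
  cyl <- flat_cylinder_mask(r_vox = 4, len_vox = 36, dims = c(24, 24, 44),
                            z0 = 5)
  # axis at (11, 11) world; offset by 2 voxels in x
  off <- vwi_centerline(cbind(13, 11, seq(6, 38, by = 1)), "ICA", "left")
  ref <- refine_with_lumen(off, cyl)
  d_axis <- sqrt((ref$points[, 1] - 11)^2 + (ref$points[, 2] - 11)^2)
  expect_lt(max(d_axis), 0.5)
  # already-centred line stays put
  ctr <- vwi_centerline(cbind(11, 11, seq(6, 38, by = 1)), "ICA", "left")
  ref2 <- refine_with_lumen(ctr, cyl)
  expect_lt(max(abs(ref2$points[, 1:2] - 11)), 0.25)
  # mostly outside the lumen: refused with a warning
  out <- vwi_centerline(cbind(2, 2, seq(6, 38, by = 1)), "ICA", "left")
  expect_warning(ref3 <- refine_with_lumen(out, cyl), "refused")
  expect_identical(ref3$points, out$points)
})

test_that("refinement flags spans crossing an empty lumen", {
  ph <- generate_phantom(spec_single_tube(23))
  len <- centerline_length(ph$centerlines[[1]])
  gapped <- gap_mask(ph, 1, c(len / 2 - 3, len / 2 + 3))
  line <- ph$centerlines[[1]] # crosses the (now empty) occluded span
  ref <- refine_with_lumen(line, gapped)
  expect_true("unrefined-span" %in% ref$flags)
})
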