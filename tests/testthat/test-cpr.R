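tube <- generate_phantom(straight_tube_spec())
tube_vol <- tube$volumes$TOF
tube_line <- tube$centerlines[[1]]

test_that("straightened CPR of a straight tube equals the direct slice oracle", {
  cp <- straightened_cpr(tube_vol, tube_line, half_width_mm = 6, step_mm = 0.6)
  pts <- vwikit:::resample_polyline(tube_line$points, 0.6)
  offv <- seq(-ceiling(6 / 0.6), ceiling(6 / 0.6)) * 0.6
  for (i in seq(1, nrow(pts), by = 7)) {
    pos <- cbind(pts[i, 1] + offv, pts[i, 2], pts[i, 3])
    v <- vwikit:::cpp_trilinear(tube_vol$data, dim(tube_vol$data),
                                vwikit:::world_to_voxel(pos, tube_vol$spacing),
                                min(tube_vol$data))$values
    expect_equal(unname(cp$pixels[i, ]), unname(v), tolerance = 1e-6)
  }
})

test_that("CPR of a uniform volume is uniform and shapes follow the contract", {
  uv <- vwi_volume(array(7, c(32, 32, 32)), c(1, 1, 1), "TOF")
  line <- vwi_centerline(rbind(c(8, 8, 4), c(20, 17, 27)), "ICA")
  cp <- straightened_cpr(uv, line, half_width_mm = 3, step_mm = 1)
  expect_true(all(abs(cp$pixels[!cp$outside] - 7) < 1e-9))
  L <- centerline_length(line)
  expect_identical(nrow(cp$pixels), as.integer(ceiling(L / 1)) + 1L)
  expect_identical(ncol(cp$pixels), 2L * as.integer(ceiling(3 / 1)) + 1L)
  expect_error(straightened_cpr(uv, vwi_centerline(matrix(c(1, 1, 1), 1), "ICA")),
               "too short")
})

test_that("0 and 180 degree CPRs are mirror images", {
  cp0 <- straightened_cpr(tube_vol, tube_line, half_width_mm = 6,
                          step_mm = 0.6, angle_deg = 0)
  cp180 <- straightened_cpr(tube_vol, tube_line, half_width_mm = 6,
                            step_mm = 0.6, angle_deg = 180)
  expect_equal(cp0$pixels, cp180$pixels[, ncol(cp180$pixels):1],
               tolerance = 1e-9)
})

test_that("transported frames are orthonormal and never flip", {
  t_ <- seq(0, 3, length.out = 120)
  curve <- cbind(10 + 6 * sin(t_), 10 + 4 * cos(1.3 * t_), 3 + 9 * t_)
  fr <- moving_frames(curve)
  for (f in fr) expect_equal(rowSums(f^2), rep(1, nrow(curve)), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(fr$tangent * fr$normal))), 1e-9)
  dots <- rowSums(fr$normal[-1, ] * fr$normal[-nrow(curve), ])
  expect_gt(min(dots), 0)
})

test_that("deviation fraction measures the arc outside the lumen", {
  expect_equal(deviation_fraction(tube_line, tube$mask), 0.0)
  outside <- vwi_centerline(tube_line$points + 10, "ICA", "left")
  expect_equal(deviation_fraction(outside, tube$mask), 1.0)
  # half in, half out: straight line leaving the tube halfway
  n <- 80
  half <- vwi_centerline(cbind(c(rep(19.8, n / 2), seq(19.8, 36, length.out = n / 2)),
                               19.8, seq(3, 35, length.out = n)), "ICA", "left")
  dev <- deviation_fraction(half, tube$mask)
  expect_gt(dev, 0.3); expect_lt(dev, 0.6)
  # reparameterization invariance: doubling sampling density barely moves it
  expect_lt(abs(deviation_fraction(half, tube$mask, sample_mm = 0.125) -
                  deviation_fraction(half, tube$mask, sample_mm = 0.25)), 0.02)
  # empty target label
  expect_warning(d1 <- deviation_fraction(
    vwi_centerline(tube_line$points, "MCA", "left"), tube$mask), "empty")
  expect_equal(d1, 1.0)
})

test_that("the quantitative rubric reproduces the 25%/50% thresholds", {
  expect_identical(rubric_score(0, TRUE), 1L)
  expect_identical(rubric_score(0.10, TRUE), 2L)
  expect_identical(rubric_score(0.25, TRUE), 2L)
  expect_identical(rubric_score(0.30, TRUE), 3L)
  expect_identical(rubric_score(0.50, TRUE), 3L)
  expect_identical(rubric_score(0.51, TRUE), 4L)
  expect_identical(rubric_score(0.10, FALSE), 4L)
  expect_error(rubric_score(1.2, TRUE))
})
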