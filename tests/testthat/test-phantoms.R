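test_that("rasterized straight tube matches the exact distance oracle", {
  ph <- generate_phantom(straight_tube_spec())
  # oracle: voxels within radius of the analytic axis segment
  dm <- dim(ph$mask$data); sp <- ph$mask$spacing
  idx <- arrayInd(seq_len(prod(dm)), dm)
  w <- sweep(idx - 1, 2, sp, "*")
  seg0 <- c(19.8, 19.8, 2); seg1 <- c(19.8, 19.8, 36)
  tpar <- pmin(1, pmax(0, ((w - rep(seg0, each = nrow(w))) %*%
                             (seg1 - seg0)) / sum((seg1 - seg0)^2)))
  proj <- rep(seg0, each = nrow(w)) + tpar %*% t(seg1 - seg0)
  d <- sqrt(rowSums((w - proj)^2))
  # the rasterizer samples the curve every quarter voxel, so it nests
  # between the exact oracles at radius -/+ half a sample step
  step <- 0.25 * 0.6
  got <- array(ph$mask$data > 0, dm)
  expect_true(all(got[d <= 1.8 - step / 2]))   # inner oracle subset of mask
  expect_true(all(d[got] <= 1.8 + 1e-9))       # mask subset of outer oracle
  expect_lt(mean(xor(got, d <= 1.8)), 0.01)    # near-exact agreement
  # voxel count within 10% of the analytic cylinder volume pi r^2 L
  # (in voxels: r = 3, L = 34/0.6; the rounded end caps add ~9%)
  analytic <- pi * 3^2 * (34 / 0.6)
  expect_lt(abs(sum(got) - analytic) / analytic, 0.10 + 0.09)
})

test_that("identical spec and seed give bit-identical phantoms", {
  s1 <- generate_phantom(spec_bifurcation(4))
  s2 <- generate_phantom(spec_bifurcation(4))
  for (kd in names(s1$volumes))
    expect_identical(s1$volumes[[kd]]$data, s2$volumes[[kd]]$data)
  expect_identical(s1$mask$data, s2$mask$data)
  expect_identical(s1$centerlines[[1]]$points, s2$centerlines[[1]]$points)
})

test_that("occluded spans vanish on TOF but stay delineated on black-blood", {
  spec <- straight_tube_spec(noise = 0, occlusion_span = c(12, 22))
  ph <- generate_phantom(spec)
  occ <- ph$branch_idx == 1 & !is.na(ph$branch_arc) &
    ph$branch_arc >= 12 & ph$branch_arc <= 22
  expect_gt(sum(occ), 100)
  expect_equal(unique(as.numeric(ph$volumes$TOF$data[occ])),
               unname(spec$background_level[["TOF"]]))
  expect_equal(unique(as.numeric(ph$volumes$T1WI$data[occ])),
               unname(spec$wall_level[["T1WI"]]))
  expect_true(all(ph$mask$data[occ] > 0)) # the vessel itself still exists
})

test_that("invalid phantom specs are rejected with informative errors", {
  expect_error(phantom_spec(grid_shape = c(8, 64, 64)), ">= 16")
  expect_error(vwi_branch("XYZ", "left", rbind(c(0, 0, 0), c(1, 1, 1)), 1),
               "unknown artery")
  expect_error(vwi_branch("ICA", "left", rbind(c(0, 0, 0), c(1, 1, 1)), -1),
               "positive")
  # branch exits the grid: error names the branch
  sp <- phantom_spec(branches = list(
    vwi_branch("ICA", "left", rbind(c(1, 19, 2), c(1, 19, 36)), 3)))
  expect_error(generate_phantom(sp), "ICA/left exits")
  # mid-course crossing of different labels
  sp2 <- phantom_spec(branches = list(
    vwi_branch("ICA", "left", rbind(c(10, 19, 5), c(30, 19, 33)), 2),
    vwi_branch("ECA", "left", rbind(c(30, 19, 5), c(10, 19, 33)), 2)))
  expect_error(generate_phantom(sp2), "overlap")
  # occlusion span outside arc length
  expect_error(generate_phantom(straight_tube_spec(occlusion_span = c(30, 60))),
               "occlusion_span")
})

test_that("phantom spec YAML roundtrip preserves the generated sample", {
  spec <- spec_head_neck(6)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  spec2 <- read_phantom_spec(path)
  s1 <- generate_phantom(spec)
  s2 <- generate_phantom(spec2)
  expect_identical(s1$mask$data, s2$mask$data)
  expect_identical(s1$volumes$TOF$data, s2$volumes$TOF$data)
})
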