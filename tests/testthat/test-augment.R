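sample_hn <- generate_phantom(spec_head_neck(3))

test_that("default augmentation yields exactly six samples per input", {
  out <- augment_phantom(sample_hn)
  expect_length(out, 6L)
  expect_identical(out[[1]]$mask$data, sample_hn$mask$data) # original first
})

test_that("left-right reversal is an involution with exact side swap", {
  fl <- flip_sample(sample_hn)
  expect_setequal(paste(fl$mask$labels$artery), paste(sample_hn$mask$labels$artery))
  swap <- c(left = "right", right = "left", midline = "midline")
  expect_identical(unname(swap[sample_hn$mask$labels$side]), fl$mask$labels$side)
  back <- flip_sample(fl)
  for (kd in names(sample_hn$volumes))
    expect_identical(back$volumes[[kd]]$data, sample_hn$volumes[[kd]]$data)
  expect_identical(back$mask$data, sample_hn$mask$data)
  expect_identical(back$mask$labels, sample_hn$mask$labels)
  for (i in seq_along(sample_hn$centerlines)) {
    # coordinates are restored to floating-point rounding of the mirror map
    expect_equal(back$centerlines[[i]]$points, sample_hn$centerlines[[i]]$points,
                 tolerance = 1e-12)
    expect_identical(back$centerlines[[i]]$side, sample_hn$centerlines[[i]]$side)
  }
})

test_that("displacement shifts centerlines by exactly shift * spacing", {
  shift <- c(5L, 0L, 0L)
  tr <- translate_sample(sample_hn, shift)
  sp <- sample_hn$mask$spacing
  for (i in seq_along(sample_hn$centerlines)) {
    # oracle: apply the translation to the truth centerline independently
    expected <- sweep(sample_hn$centerlines[[i]]$points, 2, shift * sp, "+")
    expect_equal(tr$centerlines[[i]]$points, expected, tolerance = 1e-12)
  }
  # paired transform: image content shifts identically
  expect_identical(tr$mask$data[6:64, , ], sample_hn$mask$data[1:59, , ])
})

test_that("after augmentation, thresholding noiseless TOF reproduces the mask", {
  s0 <- generate_phantom(spec_head_neck(8, occluded_prob = 0, noise_sigma = 0))
  thr <- mean(c(s0$spec$background_level[["TOF"]], s0$spec$lumen_level[["TOF"]]))
  for (tr in list(translate_sample(s0, c(3L, -2L, 4L)), flip_sample(s0),
                  truncate_sample(s0, list(lo = c(9L, 9L, 9L),
                                           hi = c(56L, 56L, 56L))))) {
    expect_identical(tr$volumes$TOF$data > thr, tr$mask$data > 0)
  }
})

test_that("occlusion augmentation suppresses TOF signal over an arc span only", {
  s0 <- generate_phantom(spec_single_tube(5, occluded = FALSE, noise_sigma = 0))
  oc <- occlude_sample(s0, branch = 1, span = c(10, 16))
  sel <- s0$branch_idx == 1 & !is.na(s0$branch_arc) &
    s0$branch_arc >= 10 & s0$branch_arc <= 16
  expect_equal(unique(as.numeric(oc$volumes$TOF$data[sel])),
               unname(s0$spec$background_level[["TOF"]]))
  untouched <- s0$mask$data > 0 & !sel
  expect_identical(oc$volumes$TOF$data[untouched], s0$volumes$TOF$data[untouched])
  expect_identical(oc$mask$data, s0$mask$data)
})

test_that("truncation keeps vessel content and re-expresses coordinates", {
  tr <- truncate_sample(sample_hn, list(lo = c(9L, 9L, 9L), hi = c(56L, 56L, 56L)))
  expect_identical(dim(tr$mask$data), c(48L, 48L, 48L))
  expect_gt(sum(tr$mask$data > 0), 0)
  # cropped centerlines lie inside the new grid
  for (cl in tr$centerlines) {
    ext <- (dim(tr$mask$data) - 1) * tr$mask$spacing
    expect_true(all(cl$points >= -1e-9) &&
                  all(sweep(cl$points, 2, ext) <= 1e-9))
  }
})
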