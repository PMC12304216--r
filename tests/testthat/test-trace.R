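test_that("trace_path matches the exhaustive shortest-path oracle exactly", {
  set.seed(31)
  for (rep in 1:4) {
    dm <- sample(8:12, 3, replace = TRUE)
    sp <- runif(3, 0.4, 1.0)
    fld <- list(data = array(runif(prod(dm)) + 0.05, dm), spacing = sp)
    s <- vapply(dm, function(n) sample.int(n, 1), 1L)
    e <- vapply(dm, function(n) sample.int(n, 1), 1L)
    if (all(s == e)) e[1] <- max(1L, e[1] - 1L)
    oc <- trace_cost_oracle(fld, s, e)
    tp <- trace_path(fld, (s - 1) * sp, (e - 1) * sp)
    expect_s3_class(tp, "vwi_centerline")
    expect_equal(attr(tp, "cost"), oc, tolerance = 1e-9)
  }
})

test_that("tracing through a tube's distance field stays near the axis", {
  cyl <- flat_cylinder_mask(r_vox = 4, len_vox = 36, dims = c(24, 24, 44),
                            z0 = 5)
  fld <- distance_field(cyl)
  tp <- trace_path(fld, c(11, 11, 6), c(11, 11, 39))
  d_axis <- sqrt((tp$points[, 1] - 11)^2 + (tp$points[, 2] - 11)^2)
  expect_lte(max(d_axis), 1 + 1e-9) # within 1 voxel of the axis
})

test_that("degenerate and untraceable cases are distinguishable", {
  fld <- list(data = array(1, c(8, 8, 8)), spacing = c(1, 1, 1))
  p <- c(2, 2, 2)
  tp <- trace_path(fld, p, p)
  expect_identical(nrow(tp$points), 1L)
  expect_equal(centerline_length(tp), 0)
  un <- trace_path(fld, c(0, 0, 0), c(7, 7, 7), max_cost = 1e-4)
  expect_s3_class(un, "vwi_untraceable")
  expect_error(trace_path(fld, c(-5, 0, 0), p), "outside")
})

test_that("path tracing is deterministic under cost ties", {
  fld <- list(data = array(1, c(9, 9, 9)), spacing = c(1, 1, 1))
  t1 <- trace_path(fld, c(1, 1, 1), c(7, 7, 7))
  t2 <- trace_path(fld, c(1, 1, 1), c(7, 7, 7))
  expect_identical(t1$points, t2$points)
})
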