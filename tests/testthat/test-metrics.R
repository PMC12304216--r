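test_that("dice coefficient matches set arithmetic and handles edge cases", {
  x <- array(FALSE, c(3, 3, 3)); y <- x
  x[1:3, 1, 1] <- TRUE          # |X| = 3
  y[2:3, 1, 1] <- TRUE; y[1, 2, 1] <- TRUE  # |Y| = 3, overlap 2
  expect_equal(dice_coefficient(x, y), 2 * 2 / 6)
  expect_equal(dice_coefficient(x, x), 1.0)
  z <- array(FALSE, c(3, 3, 3)); z[3, 3, 3] <- TRUE
  expect_equal(dice_coefficient(x, z), 0.0)
  expect_equal(dice_coefficient(array(FALSE, c(2, 2, 2)),
                                array(FALSE, c(2, 2, 2))), 1.0)
  expect_error(dice_coefficient(x, array(FALSE, c(4, 4, 4))), "mismatch")
})

test_that("dice agrees with a naive double-loop oracle on random small masks", {
  set.seed(101)
  for (rep in 1:25) {
    dm <- sample(2:6, 3, replace = TRUE)
    x <- array(runif(prod(dm)) < 0.4, dm)
    y <- array(runif(prod(dm)) < 0.4, dm)
    xi <- which(x); yi <- which(y)
    oracle <- if (length(xi) + length(yi) == 0) 1 else {
      inter <- 0
      for (v in xi) for (w in yi) if (v == w) inter <- inter + 1
      2 * inter / (length(xi) + length(yi))
    }
    expect_equal(dice_coefficient(x, y), oracle, tolerance = 1e-12)
  }
})

test_that("mcd reproduces hand-computed and exhaustive oracle values", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 1, 0), c(1, 1, 0))
  expect_equal(mcd(a, b), 1.0)
  expect_equal(mcd(a, a), 0.0)
  expect_equal(mcd(matrix(c(0, 0, 0), 1), matrix(c(0, 1.5, 2), 1)), 2.5)
  expect_error(mcd(a, matrix(numeric(0), 0, 3)), "empty")
  set.seed(7)
  for (rep in 1:10) {
    na <- sample(1:200, 1); nb <- sample(1:200, 1)
    A <- matrix(rnorm(3 * na), ncol = 3)
    B <- matrix(rnorm(3 * nb), ncol = 3)
    expect_equal(mcd(A, B), mcd_oracle(A, B), tolerance = 1e-9)
    expect_equal(mcd(A, B), mcd(B, A), tolerance = 1e-12)  # symmetry
  }
})

test_that("centerline accuracy measures recovered fraction of truth length", {
  truth <- vwi_centerline(cbind(0, 0, seq(0, 20, by = 0.5)), "ICA")
  expect_equal(centerline_accuracy(truth, truth), 1.0)
  far <- vwi_centerline(cbind(10, 10, seq(0, 20, by = 0.5)), "ICA")
  expect_equal(centerline_accuracy(far, truth), 0.0)
  half <- vwi_centerline(cbind(0, 0, seq(0, 10, by = 0.5)), "ICA")
  expect_equal(centerline_accuracy(half, truth), 0.5, tolerance = 0.01)
  expect_error(centerline_accuracy(truth, matrix(c(1, 1, 1), 1)), "zero-length")
})

test_that("centerline accuracy is monotone non-increasing as tolerance shrinks", {
  set.seed(11)
  truth <- vwi_centerline(cbind(sin(seq(0, 2, 0.1)), 0, seq(0, 20, by = 1)), "ICA")
  noisy <- vwi_centerline(truth$points + matrix(rnorm(nrow(truth$points) * 3, 0, 0.5),
                                                ncol = 3), "ICA")
  tols <- c(3, 2, 1, 0.5, 0.25)
  accs <- vapply(tols, function(tl) centerline_accuracy(noisy, truth, tol_mm = tl), 0)
  expect_true(all(diff(accs) <= 1e-12))
})

test_that("mcd on centerlines is stable under resampling density", {
  cl1 <- vwi_centerline(cbind(0, 0, seq(0, 30, by = 5)), "ICA")   # sparse
  cl2 <- vwi_centerline(cbind(0.4, 0, seq(0, 30, by = 0.2)), "ICA") # dense
  m_default <- mcd(cl1, cl2)
  m_fine <- mcd(cl1, cl2, sample_mm = 0.25)
  expect_equal(m_default, 0.4, tolerance = 0.02)
  expect_equal(m_default, m_fine, tolerance = 0.02)
})
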