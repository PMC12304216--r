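test_that("forward pass obeys the shape contract and normalisation", {
  set.seed(5)
  model <- build_model(net_config(2L, 9L, base_width = 8L, n_scales = 4L))
  dm <- c(32L, 32L, 32L)
  x <- list(mat = matrix(rnorm(2 * prod(dm)), 2), dims = dm)
  out <- vwikit:::net_forward(model, vwikit:::add_coord_channels(x),
                              want_cache = FALSE)$out
  expect_identical(nrow(out$mat), 9L)
  expect_identical(out$dims, dm)
  p <- vwikit:::softmax_cols(out$mat)
  expect_lt(max(abs(colSums(p) - 1)), 1e-5)
  # non-multiple grids are padded then cropped back
  pr <- vwikit:::infer_prob(model, list(mat = matrix(rnorm(2 * 27000), 2),
                                        dims = c(30L, 30L, 30L)))
  expect_identical(ncol(pr$mat), 27000L)
})

test_that("analytic gradients match finite differences", {
  set.seed(12)
  model <- build_model(net_config(2L, 3L, base_width = 8L, n_scales = 2L,
                                  coords = FALSE))
  dm <- c(8L, 8L, 8L)
  x <- list(mat = matrix(rnorm(2 * prod(dm)), 2), dims = dm)
  g <- vwikit:::onehot_cols(sample(0:2, prod(dm), TRUE), 3L)
  fw <- vwikit:::net_forward(model, x)
  p <- vwikit:::softmax_cols(fw$out$mat)
  lg <- vwikit:::dice_loss_grad(p, g)
  dz <- vwikit:::softmax_backward(p, lg$grad)
  bw <- vwikit:::net_backward(model, fw$caches, list(mat = dz, dims = dm))
  gr <- vwikit:::flatten_grads(bw$grads, model$layers)
  par <- vwikit:::flatten_params(model$layers)
  lossfun <- function(flat) {
    m2 <- model
    m2$layers <- vwikit:::assign_params(model$layers, flat)
    fw2 <- vwikit:::net_forward(m2, x, want_cache = FALSE)
    vwikit:::dice_loss_grad(vwikit:::softmax_cols(fw2$out$mat), g,
                            want_grad = FALSE)$loss
  }
  h <- 1e-5
  set.seed(3)
  for (k in sample(names(par), 8)) {
    i <- sample(length(par[[k]]), 1)
    pp <- par
    pp[[k]][i] <- pp[[k]][i] + h; lp <- lossfun(pp)
    pp[[k]][i] <- pp[[k]][i] - 2 * h; lm <- lossfun(pp)
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(fd - gr[[k]][i]) / max(1e-6, abs(fd) + abs(gr[[k]][i])),
              1e-4)
  }
})

test_that("soft Dice loss reproduces closed-form values", {
  g <- vwikit:::onehot_cols(c(0L, 1L, 1L, 0L), 2L)
  expect_lt(dice_loss(g, g), 1e-4)                      # perfect overlap
  comp <- g[2:1, ]                                       # complement
  expect_equal(dice_loss(comp, g), 1, tolerance = 1e-4)
  unif <- matrix(0.5, 2, 4)                              # fg fraction 0.5
  expect_equal(dice_loss(unif, g), 0.5, tolerance = 1e-4)
  # class with empty target foreground is skipped from the average
  g3 <- vwikit:::onehot_cols(c(0L, 1L, 1L, 0L), 3L)
  expect_lt(dice_loss(g3, g3), 1e-4)
})

test_that("channel preparation implements the sequence-fallback contract", {
  ph <- generate_phantom(spec_single_tube(2))
  # single black-blood sequence is duplicated into both channels
  prep <- prepare_channels(ph$volumes["T1WI"], "black")
  expect_identical(prep$mat[1, ], prep$mat[2, ])
  expect_identical(prep$channel_reference, "T1WI")
  # both present: channel 1 = T1WI, channel 2 = T1WI-CE
  prep2 <- prepare_channels(ph$volumes[c("T1WI", "T1WI-CE")], "black")
  expect_false(identical(prep2$mat[1, ], prep2$mat[2, ]))
  # z-scoring within the body mask
  expect_lt(abs(mean(prep$mat[1, vwikit:::body_mask(ph$volumes$T1WI$data)])), 1e-9)
  # TOF-only: black path unavailable, bright path selected
  expect_null(prepare_channels(ph$volumes["TOF"], "black"))
  expect_identical(nrow(prepare_channels(ph$volumes["TOF"], "bright")$mat), 1L)
  expect_error(prepare_channels(list(), "black"), "no usable sequence")
  # differing grids: channel 2 resampled onto the channel-1 frame
  small <- ph$volumes$`T1WI-CE`
  small$data <- small$data[seq(1, 64, by = 2), seq(1, 64, by = 2),
                           seq(1, 64, by = 2)]
  small$spacing <- ph$volumes$T1WI$spacing * 2
  prep3 <- prepare_channels(list("T1WI" = ph$volumes$T1WI,
                                 "T1WI-CE" = small), "black")
  expect_identical(prep3$dims, dim(ph$volumes$T1WI$data))
})

test_that("fusion follows max-probability with the occlusion-candidate rule", {
  labels <- data.frame(id = 1:2, artery = c("ICA", "ECA"), side = "left",
                       stringsAsFactors = FALSE)
  mkseg <- function(prob) {
    lab <- array(max.col(t(prob)) - 1L, c(3, 3, 3))
    structure(list(prob = prob, dims = c(3L, 3L, 3L), spacing = c(1, 1, 1),
                   mask = vwi_mask(lab, c(1, 1, 1), labels),
                   channel_reference = "T1WI"), class = "vwi_segmentation")
  }
  n <- 27
  base <- rbind(rep(0.9, n), rep(0.05, n), rep(0.05, n))
  # identical inputs -> either input's mask
  s <- mkseg(base)
  expect_identical(fuse_segmentations(s, s)$data, s$mask$data)
  # conflicting voxel: black ICA 0.6 vs bright ECA 0.9 -> ECA (max prob)
  pb <- base; pb[, 14] <- c(0.3, 0.6, 0.1)
  pr <- base; pr[, 14] <- c(0.05, 0.05, 0.9)
  fused <- fuse_segmentations(mkseg(pb), mkseg(pr))
  expect_identical(as.integer(fused$data[14]), 2L)
  # occlusion candidate: black foreground, bright background -> black wins
  pb2 <- base; pb2[, 14] <- c(0.2, 0.7, 0.1)
  pr2 <- base; pr2[, 14] <- c(0.8, 0.1, 0.1)
  fused2 <- fuse_segmentations(mkseg(pb2), mkseg(pr2))
  expect_identical(as.integer(fused2$data[14]), 1L)
  # degenerate fusion: empty bright output defers to black
  expect_identical(fuse_segmentations(mkseg(pb2), NULL)$data,
                   mkseg(pb2)$mask$data)
  # frame mismatch is an error, never a silent resample
  s2 <- mkseg(base); s2$spacing <- c(2, 2, 2)
  expect_error(fuse_segmentations(s, s2), "frame mismatch")
})

test_that("zero-epoch training returns the model unchanged", {
  set.seed(8)
  model <- build_model(net_config(1L, 2L, base_width = 8L, n_scales = 2L))
  ph <- generate_phantom(spec_single_tube(3, noise = 2))
  prep <- prepare_channels(ph$volumes, "bright")
  data <- list(list(input = prep, target = (ph$mask$data > 0) * 1L))
  fit <- train_model(model, data, hyper = train_config(epochs = 0L))
  expect_identical(vwikit:::flatten_params(fit$model$layers),
                   vwikit:::flatten_params(model$layers))
  expect_identical(nrow(fit$history), 0L)
})

test_that("checkpoints round-trip the model exactly", {
  set.seed(9)
  model <- build_model(net_config(2L, 4L, base_width = 8L, n_scales = 2L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  m2 <- load_checkpoint(path)
  expect_identical(vwikit:::flatten_params(m2$layers),
                   vwikit:::flatten_params(model$layers))
  expect_identical(unclass(m2$config), unclass(model$config))
})
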