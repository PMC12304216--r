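# Training behaviour properties at reduced scale (binary tube task on small
# grids so three dataset sizes x three seeds stay cheap).

mk_small <- function(sd) {
  s <- generate_phantom(spec_single_tube(sd, grid_shape = c(32, 32, 32),
                                         spacing_mm = c(1.2, 1.2, 1.2)))
  list(input = prepare_channels(s$volumes, "bright"),
       target = (s$mask$data > 0) * 1L)
}

test_that("held-out Dice improves with training-set size", {
  sizes <- c(5, 10, 20)
  inversions <- 0
  for (rs in 1:3) {
    va <- lapply(rs * 1000L + 51:54, mk_small)
    dices <- vapply(sizes, function(nn) {
      tr <- lapply(rs * 1000L + seq_len(nn), mk_small)
      set.seed(rs)
      fit <- train_model(build_model(net_config(1L, 2L)), tr,
                         hyper = train_config(epochs = 10L,
                                              patch = c(16L, 16L, 16L),
                                              patches_per_epoch = 2L,
                                              lr_decay = 0.995, seed = rs))
      mean(vapply(va, function(smp)
        vwikit:::foreground_dice(vwikit:::infer_labels(fit$model, smp$input),
                                 smp$target), 0))
    }, 0)
    inversions <- inversions + sum(diff(dices) < 0)
  }
  expect_lte(inversions, 1)
})

test_that("overfitting two samples drives the training loss monotonically down early", {
  tr <- lapply(71:72, mk_small)
  set.seed(4)
  fit <- train_model(build_model(net_config(1L, 2L)), tr,
                     hyper = train_config(epochs = 30L,
                                          patch = c(16L, 16L, 16L),
                                          patches_per_epoch = 4L, seed = 4))
  h <- fit$history$train_loss
  # early epochs: loss at k+10 below loss at k (smoothed one-sided check)
  expect_lt(h[11], h[1])
  expect_lt(h[21], h[11])
  expect_lt(mean(tail(h, 5)), 0.2)
})
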