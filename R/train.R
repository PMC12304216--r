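# Training (soft-Dice supervision, Adam with exponential learning-rate
# decay), channel preparation with sequence-fallback logic, full-volume
# inference and probability fusion.

softmax_cols <- function(z) {
  zmax <- do.call(pmax, lapply(seq_len(nrow(z)), function(r) z[r, ]))
  e <- exp(z - rep(zmax, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

onehot_cols <- function(labels, n_classes) {
  n <- length(labels)
  oh <- matrix(0, n_classes, n)
  oh[cbind(labels + 1L, seq_len(n))] <- 1
  oh
}

#' Soft Dice loss
#'
#' `1 - soft Dice`, where soft Dice is `2 sum(p*g) / (sum(p) + sum(g) + eps)`
#' averaged over the foreground classes present in the target; classes with
#' empty target foreground are skipped (eps guards the division).
#'
#' @param prob Class-probability grid: `n_classes x n_voxels` matrix or a 4D
#'   array with classes first.
#' @param target One-hot grid of the same shape.
#' @param eps Stabiliser (default 1e-5).
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prob, target, eps = 1e-5) {
  p <- if (is.matrix(prob)) prob else matrix(prob, dim(prob)[1])
  g <- if (is.matrix(target)) target else matrix(target, dim(target)[1])
  stopifnot(all(dim(p) == dim(g)))
  dice_loss_grad(p, g, eps, want_grad = FALSE)$loss
}

# loss + d(loss)/d(prob); foreground classes are rows 2..C. Training sets
# include_background: with several artery classes and foreground-only
# averaging, every crop that pushes one class down on background voxels
# passively pushes the others up there (softmax coupling) and the background
# class collapses; scoring the background class too restores the balance.
dice_loss_grad <- function(p, g, eps = 1e-5, want_grad = TRUE,
                           include_background = FALSE) {
  C <- nrow(p)
  fg <- which(rowSums(g[-1, , drop = FALSE]) > 0) + 1L
  if (include_background) fg <- c(1L, fg)
  if (length(fg) == 0)
    return(list(loss = 0, grad = if (want_grad) matrix(0, nrow(p), ncol(p))))
  num <- 2 * rowSums(p[fg, , drop = FALSE] * g[fg, , drop = FALSE])
  den <- rowSums(p[fg, , drop = FALSE]) + rowSums(g[fg, , drop = FALSE]) + eps
  soft <- num / den
  loss <- 1 - mean(soft)
  grad <- NULL
  if (want_grad) {
    grad <- matrix(0, nrow(p), ncol(p))
    K <- length(fg)
    # d(1 - mean(num/den))/dp_c = -(2*g_c*den - num) / (K * den^2)
    grad[fg, ] <- -(2 * g[fg, , drop = FALSE] * den - num) / (K * den^2)
  }
  list(loss = loss, grad = grad)
}

# backprop through per-voxel softmax
softmax_backward <- function(p, dp) {
  p * (dp - matrix(colSums(dp * p), nrow(p), ncol(p), byrow = TRUE))
}

#' Training hyper-parameters
#'
#' Defaults: Adam with first-moment coefficient 0.9, initial learning rate
#' 1e-3, exponential learning-rate decay (0.97 per epoch) and weight decay
#' 1e-5; patch-based sampling with crops biased to vessel voxels.
#'
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param beta1,beta2 Adam moment coefficients.
#' @param weight_decay Decoupled weight decay.
#' @param lr_decay Per-epoch exponential decay factor.
#' @param clip_norm Global gradient-norm clip; crops containing only a
#'   sliver of foreground otherwise produce exploding Dice-loss gradients.
#' @param ce_weight Weight of the auxiliary cross-entropy term. The Dice
#'   term gives exactly zero gradient to classes absent from a crop, so with
#'   patch-based training probability leaks onto absent artery classes;
#'   cross-entropy supervises every class on every voxel and stops the leak.
#' @param patch Patch size (voxels, multiple of 2^n_scales).
#' @param patches_per_epoch Crops drawn per training sample per epoch.
#' @param fg_bias Probability a training crop is centred on a vessel voxel.
#' @param val_every Validate every this many epochs.
#' @param seed RNG seed for sampling and any reinitialisation.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 60L, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-5, lr_decay = 0.97,
                         patch = c(32L, 32L, 32L), patches_per_epoch = 2L,
                         fg_bias = 0.9, val_every = 5L, clip_norm = 1,
                         ce_weight = 0.5, seed = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, weight_decay = weight_decay,
                 lr_decay = lr_decay, patch = as.integer(patch),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 fg_bias = fg_bias, val_every = as.integer(val_every),
                 clip_norm = clip_norm, ce_weight = ce_weight,
                 seed = as.integer(seed)),
            class = "train_config")
}

# half-overlap tiling of a grid by windows (shared by training sampling and
# sliding-window inference, so the two see identical input distributions)
tile_starts <- function(d, window) {
  lapply(1:3, function(ax) {
    st <- unique(c(seq(1L, max(1L, d[ax] - window[ax] + 1L),
                       by = max(1L, window[ax] %/% 2L)),
                   d[ax] - window[ax] + 1L))
    st[st >= 1L]
  })
}

# Tiling of a target grid with per-tile vessel-presence flags (cached per
# sample by train_model; scanning the target for every crop dominates the
# step time otherwise).
tile_fg_index <- function(target, patch) {
  d <- dim(target)
  patch <- pmin(patch, d)
  st <- tile_starts(d, patch)
  tiles <- as.matrix(expand.grid(st[[1]], st[[2]], st[[3]]))
  has_fg <- vapply(seq_len(nrow(tiles)), function(r) {
    lo <- tiles[r, ]
    any(target[lo[1]:(lo[1] + patch[1] - 1L), lo[2]:(lo[2] + patch[2] - 1L),
               lo[3]:(lo[3] + patch[3] - 1L)] > 0)
  }, TRUE)
  list(tiles = tiles, has_fg = has_fg)
}

# Random training crop drawn from the inference tiling (vessel-containing
# tiles with probability fg_bias); returns input (+ coordinate channels) and
# one-hot target matrices. Aligning crop positions with the inference tiling
# keeps the instance-normalization statistics identical between training and
# sliding-window prediction.
sample_patch <- function(input, target, patch, fg_bias, n_classes,
                         coords = TRUE, tiles_fg = NULL) {
  d <- input$dims
  patch <- pmin(patch, d)
  if (is.null(tiles_fg)) tiles_fg <- tile_fg_index(target, patch)
  tiles <- tiles_fg$tiles
  has_fg <- tiles_fg$has_fg
  pick <- if (any(has_fg) && runif(1) < fg_bias) which(has_fg) else
    seq_len(nrow(tiles))
  lo <- tiles[pick[sample.int(length(pick), 1)], ]
  hi <- lo + patch - 1L
  arr <- array(input$mat, c(nrow(input$mat), d))
  xin <- arr[, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  tgt <- target[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  x <- list(mat = matrix(xin, nrow(input$mat), prod(patch)), dims = patch)
  if (coords) x <- add_coord_channels(x, origin = lo - 1L, full_dims = d)
  list(x = x, g = onehot_cols(as.integer(tgt), n_classes))
}

#' Train a segmentation network
#'
#' Dice-loss supervision with the Adam optimizer (momentum 0.9, initial
#' learning rate 1e-3, exponential decay, weight decay 1e-5 by default).
#' One vessel-biased random patch per training sample per epoch. Returns the
#' parameters with the best validation Dice (or final parameters when no
#' validation set is given) plus a per-epoch history.
#'
#' @param model A [build_model()] network.
#' @param train_data List of samples `list(input = list(mat, dims),
#'   target = integer label array)`.
#' @param val_data Optional validation samples in the same form.
#' @param hyper A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List: `model` (trained), `history` (data.frame epoch, lr,
#'   train_loss, val_dice).
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        hyper = train_config(), verbose = FALSE) {
  stopifnot(length(train_data) > 0)
  C <- model$config$n_classes
  if (hyper$epochs == 0L)
    return(list(model = model, history = data.frame(epoch = integer(0),
                                                    lr = numeric(0),
                                                    train_loss = numeric(0),
                                                    val_dice = numeric(0))))
  set.seed(hyper$seed)
  tiles_cache <- lapply(train_data, function(smp)
    tile_fg_index(smp$target, pmin(hyper$patch, smp$input$dims)))
  params <- flatten_params(model$layers)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  tstep <- 0
  lr <- hyper$lr
  best <- list(dice = -Inf, params = params)
  hist <- NULL
  for (ep in seq_len(hyper$epochs)) {
    ep_loss <- 0
    for (si in rep(sample(seq_along(train_data)), hyper$patches_per_epoch)) {
      smp <- train_data[[si]]
      pt <- sample_patch(smp$input, smp$target, hyper$patch, hyper$fg_bias, C,
                         coords = isTRUE(model$config$coords),
                         tiles_fg = tiles_cache[[si]])
      fw <- net_forward(model, pt$x)
      p <- softmax_cols(fw$out$mat)
      lg <- dice_loss_grad(p, pt$g, include_background = TRUE)
      loss <- lg$loss
      dz <- softmax_backward(p, lg$grad)
      if (hyper$ce_weight > 0) {
        nv <- ncol(p)
        loss <- loss - hyper$ce_weight *
          sum(pt$g * log(pmax(p, 1e-12))) / nv
        dz <- dz + hyper$ce_weight * (p - pt$g) / nv
      }
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d sample %d", ep, si))
      ep_loss <- ep_loss + loss
      bw <- net_backward(model, fw$caches, list(mat = dz, dims = pt$x$dims))
      g <- flatten_grads(bw$grads, model$layers)
      if (is.finite(hyper$clip_norm)) {
        gn <- sqrt(sum(vapply(g, function(x) sum(x * x), 0)))
        if (gn > hyper$clip_norm)
          g <- lapply(g, function(x) x * hyper$clip_norm / gn)
      }
      tstep <- tstep + 1
      for (k in names(params)) {
        gk <- g[[k]] + hyper$weight_decay * params[[k]]
        mstate[[k]] <- hyper$beta1 * mstate[[k]] + (1 - hyper$beta1) * gk
        vstate[[k]] <- hyper$beta2 * vstate[[k]] + (1 - hyper$beta2) * gk^2
        mhat <- mstate[[k]] / (1 - hyper$beta1^tstep)
        vhat <- vstate[[k]] / (1 - hyper$beta2^tstep)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
      model$layers <- assign_params(model$layers, params)
    }
    ep_loss <- ep_loss / (length(train_data) * hyper$patches_per_epoch)
    vd <- NA_real_
    if (!is.null(val_data) &&
        (ep %% hyper$val_every == 0L || ep == hyper$epochs)) {
      vd <- mean(vapply(val_data, function(smp) {
        pr <- infer_labels(model, smp$input, window = hyper$patch)
        foreground_dice(pr, smp$target)
      }, 0))
      if (vd > best$dice) best <- list(dice = vd, params = params)
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = ep_loss,
                                   val_dice = vd))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val_dice %s", ep, lr,
                      ep_loss, ifelse(is.na(vd), "-", sprintf("%.3f", vd))))
    lr <- lr * hyper$lr_decay
  }
  if (!is.null(val_data) && is.finite(best$dice))
    model$layers <- assign_params(model$layers, best$params)
  model$train_patch <- hyper$patch
  list(model = model, history = hist)
}

# mean Dice over foreground classes present in the truth
foreground_dice <- function(pred_labels, truth_labels) {
  cls <- setdiff(sort(unique(as.integer(truth_labels))), 0L)
  if (length(cls) == 0) return(NA_real_)
  mean(vapply(cls, function(cl)
    dice_coefficient(array(pred_labels == cl, dim(pred_labels)),
                     array(truth_labels == cl, dim(truth_labels))), 0))
}

# label inference (sliding-window by default; see infer_prob)
infer_labels <- function(model, input, window = NULL) {
  pr <- infer_prob(model, input, window)
  array(max.col(t(pr$mat)) - 1L, input$dims)
}

# Class probabilities over the full grid. Inference runs in sliding windows
# of the model's training patch size with half-window overlap and
# probability averaging: instance-norm statistics then match what the
# network saw during patch-based training (full-volume statistics differ
# enough to degrade it badly). window = NULL uses the recorded training
# patch; window = Inf forces single-pass full-volume inference.
infer_prob <- function(model, input, window = NULL) {
  m <- 2L^model$config$n_scales
  if (is.null(window)) window <- model$train_patch
  if (is.null(window) || all(!is.finite(window)) ||
      all(window >= input$dims)) {
    x <- input
    if (isTRUE(model$config$coords)) x <- add_coord_channels(x)
    pd <- pad_to_multiple(x, m)
    fw <- net_forward(model, pd$x, want_cache = FALSE)
    p <- softmax_cols(fw$out$mat)
    if (!all(pd$x$dims == input$dims))
      p <- crop_from_pad(p, pd$x$dims, input$dims)
    return(list(mat = p, dims = input$dims))
  }
  window <- pmin(as.integer(window), input$dims)
  d <- input$dims
  starts <- tile_starts(d, window)
  C <- model$config$n_classes
  acc <- matrix(0, C, prod(d))
  cnt <- numeric(prod(d))
  arr <- array(input$mat, c(nrow(input$mat), d))
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    lo <- c(sx, sy, sz); hi <- lo + window - 1L
    xin <- arr[, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    x <- list(mat = matrix(xin, nrow(input$mat), prod(window)), dims = window)
    if (isTRUE(model$config$coords))
      x <- add_coord_channels(x, origin = lo - 1L, full_dims = d)
    pd <- pad_to_multiple(x, m)
    fw <- net_forward(model, pd$x, want_cache = FALSE)
    p <- softmax_cols(fw$out$mat)
    if (!all(pd$x$dims == window)) p <- crop_from_pad(p, pd$x$dims, window)
    # scatter-accumulate into the full grid
    vox <- as.vector(outer(outer(lo[1]:hi[1],
                                 (lo[2]:hi[2] - 1) * d[1], "+"),
                           (lo[3]:hi[3] - 1) * d[1] * d[2], "+"))
    acc[, vox] <- acc[, vox] + p
    cnt[vox] <- cnt[vox] + 1
  }
  list(mat = sweep(acc, 2, pmax(1, cnt), "/"), dims = d)
}

# ---------------------------------------------------------------------------

body_mask <- function(v) {
  rng <- range(v)
  v > rng[1] + 0.1 * (rng[2] - rng[1])
}

zscore_volume <- function(v) {
  bm <- body_mask(v)
  mu <- mean(v[bm]); sd <- stats::sd(v[bm])
  if (!is.finite(sd) || sd == 0) sd <- 1
  (v - mu) / sd
}

# trilinear resampling of a volume onto a reference grid geometry
resample_to_reference <- function(vol, ref_dims, ref_spacing) {
  grid <- as.matrix(expand.grid(x = (seq_len(ref_dims[1]) - 1) * ref_spacing[1],
                                y = (seq_len(ref_dims[2]) - 1) * ref_spacing[2],
                                z = (seq_len(ref_dims[3]) - 1) * ref_spacing[3]))
  res <- cpp_trilinear(vol$data, dim(vol$data),
                       world_to_voxel(grid, vol$spacing), min(vol$data))
  vwi_volume(array(res$values, ref_dims), ref_spacing, vol$kind)
}

#' Prepare model input channels with sequence-fallback logic
#'
#' Black-blood path: channel 1 = T1WI, channel 2 = T1WI-CE; when only one of
#' the two is available it is duplicated into both channels. The spatial
#' frame is fixed to channel 1 (the first-channel alignment contract); a
#' second channel on a different grid is resampled onto it. Bright-blood
#' path: the single TOF channel. Intensities are z-scored within a body mask.
#'
#' @param available Named list of [vwi_volume] (names from
#'   [sequence_kinds()]).
#' @param path `"black"` (dual-channel black-blood) or `"bright"`
#'   (single-channel TOF).
#' @return Model-ready input: `list(mat = C x N, dims, spacing,
#'   channel_reference)`; `NULL` if the requested path has no usable
#'   sequence. Errors if neither path is usable.
#' @export
prepare_channels <- function(available, path = c("black", "bright")) {
  path <- match.arg(path)
  bb <- available[intersect(c("T1WI", "T1WI-CE"), names(available))]
  tof <- available[["TOF"]]
  if (length(bb) == 0 && is.null(tof)) stop("no usable sequence")
  if (path == "bright") {
    if (is.null(tof)) return(NULL)
    v <- zscore_volume(tof$data)
    return(list(mat = matrix(as.numeric(v), 1, length(v)), dims = dim(v),
                spacing = tof$spacing, channel_reference = "TOF"))
  }
  if (length(bb) == 0) return(NULL)
  ch1 <- bb[[1]]
  ch2 <- if (length(bb) >= 2) bb[[2]] else bb[[1]]
  if (!identical(dim(ch2$data), dim(ch1$data)) ||
      !isTRUE(all.equal(ch2$spacing, ch1$spacing)))
    ch2 <- resample_to_reference(ch2, dim(ch1$data), ch1$spacing)
  v1 <- zscore_volume(ch1$data)
  v2 <- zscore_volume(ch2$data)
  list(mat = rbind(as.numeric(v1), as.numeric(v2)), dims = dim(v1),
       spacing = ch1$spacing, channel_reference = ch1$kind)
}

#' Segment a prepared input
#'
#' Runs the network over the full grid (padded to the scale multiple and
#' cropped back) and returns per-voxel class probabilities plus the argmax
#' label grid; recognition is the per-voxel artery class of the multi-class
#' head.
#'
#' @param model A trained [build_model()] network.
#' @param prepared Output of [prepare_channels()].
#' @param labels Label table (data.frame id/artery/side) giving the meaning
#'   of classes 1..n; class 0 is background.
#' @return A `vwi_segmentation`: `prob` (classes x voxels), `mask`
#'   ([vwi_mask]), `dims`, `spacing`, `channel_reference`.
#' @export
segment_volume <- function(model, prepared, labels) {
  stopifnot(!is.null(prepared))
  if (nrow(prepared$mat) != model$config$in_channels)
    stop("channel count mismatch between model and prepared input")
  prepared <- prepared[c("mat", "dims", "spacing", "channel_reference")]
  pr <- infer_prob(model, prepared)
  lab <- array(max.col(t(pr$mat)) - 1L, prepared$dims)
  structure(list(prob = pr$mat, dims = prepared$dims,
                 spacing = prepared$spacing,
                 mask = vwi_mask(lab, prepared$spacing, labels),
                 channel_reference = prepared$channel_reference),
            class = "vwi_segmentation")
}

#' Fuse black-blood and bright-blood segmentations
#'
#' Voxelwise fusion on a shared grid: the label is the argmax over the
#' per-class maximum of the two probability maps, except at
#' occlusion-candidate voxels — foreground in the black-blood output but
#' background in the bright-blood output — where the black-blood label wins,
#' preserving occluded segments that are invisible on TOF. The rule is
#' symmetric in the two inputs up to that documented exception.
#'
#' @param black,bright `vwi_segmentation` objects on the same grid (error on
#'   frame mismatch; no silent resampling here).
#' @return Fused [vwi_mask].
#' @export
fuse_segmentations <- function(black, bright) {
  if (is.null(black)) return(bright$mask)
  if (is.null(bright)) return(black$mask)
  if (!identical(black$dims, bright$dims) ||
      !isTRUE(all.equal(black$spacing, bright$spacing)))
    stop("frame mismatch between segmentations; resample before fusing")
  pmaxm <- pmax(black$prob, bright$prob)
  lab <- max.col(t(pmaxm)) - 1L
  lb <- max.col(t(black$prob)) - 1L
  lr <- max.col(t(bright$prob)) - 1L
  occ <- lb > 0L & lr == 0L
  lab[occ] <- lb[occ]
  vwi_mask(array(lab, black$dims), black$spacing, black$mask$labels)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration and all parameters.
#' @param model A `vwi_model`.
#' @param path File path (.rds).
#' @return `load_checkpoint` returns the `vwi_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               params = flatten_params(model$layers)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(net_config, ck$config[intersect(names(ck$config),
    c("in_channels", "n_classes", "base_width", "n_scales", "norm",
      "coords"))])
  model <- build_model(cfg)
  model$layers <- assign_params(model$layers, ck$params)
  model
}
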