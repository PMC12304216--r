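# 3D segmentation-and-recognition network, implemented natively: an input
# convolution merging the (dual) input sequences, four down-sampling units of
# bottleneck residual blocks, four up-sampling units whose blocks merge the
# same-scale encoder outputs (concatenation skip connections), instance
# normalization inside the blocks, and a 1x1x1 convolution head. Convolutions
# run as im2col (C++) + BLAS GEMM; gradients are hand-derived per layer.
#
# Feature maps are lists(mat = C x N matrix, dims = c(nx, ny, nz)).

#' Network configuration
#'
#' @param in_channels 1 (bright-blood TOF) or 2 (black-blood T1WI + T1WI-CE).
#' @param n_classes Background + artery classes.
#' @param base_width Feature channels at the first scale (default 8).
#' @param n_scales Number of down/up-sampling units (default 4).
#' @param norm Use instance normalization inside blocks (default TRUE).
#' @param coords Append three normalized absolute-coordinate channels to the
#'   input internally (default TRUE). Patch-based training makes a purely
#'   translation-invariant network unable to tell left from right artery
#'   segments; the coordinate channels restore that positional information.
#'   `in_channels` still counts input sequences only.
#' @return A `net_config` list.
#' @export
net_config <- function(in_channels, n_classes, base_width = 8L,
                       n_scales = 4L, norm = TRUE, coords = TRUE) {
  stopifnot(in_channels %in% c(1L, 2L), n_classes >= 2, base_width >= 4,
            n_scales >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_width = as.integer(base_width),
                 n_scales = as.integer(n_scales), norm = isTRUE(norm),
                 coords = isTRUE(coords)),
            class = "net_config")
}

# Normalized absolute-coordinate channels for a (possibly cropped) grid:
# value = global_index / (full_dim - 1) * 2 - 1 per axis.
add_coord_channels <- function(x, origin = c(0L, 0L, 0L),
                               full_dims = x$dims) {
  d <- x$dims
  ax <- function(k) {
    v <- (origin[k] + seq_len(d[k]) - 1) / max(1, full_dims[k] - 1) * 2 - 1
    switch(k, rep(v, times = d[2] * d[3]),
           rep(rep(v, each = d[1]), times = d[3]),
           rep(v, each = d[1] * d[2]))
  }
  list(mat = rbind(x$mat, ax(1), ax(2), ax(3)), dims = d)
}

he_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

layer_conv3 <- function(cin, cout) {
  list(type = "conv3", cin = cin, cout = cout,
       params = list(W = he_mat(cout, cin * 27, cin * 27), b = numeric(cout)))
}
layer_conv1 <- function(cin, cout) {
  list(type = "conv1", cin = cin, cout = cout,
       params = list(W = he_mat(cout, cin, cin), b = numeric(cout)))
}
layer_down2 <- function(cin, cout) {
  list(type = "down2", cin = cin, cout = cout,
       params = list(W = he_mat(cout, cin * 8, cin * 8), b = numeric(cout)))
}
layer_up2 <- function(cin, cout) {
  list(type = "up2", cin = cin, cout = cout,
       params = list(W = he_mat(cout * 8, cin, cin), b = numeric(cout)))
}
layer_inorm <- function(c) {
  list(type = "inorm", c = c, params = list(g = rep(1, c), b = numeric(c)))
}

# ---- primitive forward/backward -------------------------------------------

prim_fwd <- function(layer, x) {
  switch(layer$type,
    conv3 = {
      cols <- cpp_im2col3d(x$mat, x$dims, 3L, 1L, 1L)
      y <- layer$params$W %*% cols + layer$params$b
      list(y = list(mat = y, dims = x$dims), cache = list(cols = cols, dims = x$dims))
    },
    conv1 = {
      y <- layer$params$W %*% x$mat + layer$params$b
      list(y = list(mat = y, dims = x$dims), cache = list(x = x$mat))
    },
    down2 = {
      od <- x$dims %/% 2L
      g <- cpp_gather_down2(x$mat, od)
      y <- layer$params$W %*% g + layer$params$b
      list(y = list(mat = y, dims = od), cache = list(g = g, od = od))
    },
    up2 = {
      y8 <- layer$params$W %*% x$mat
      y <- cpp_scatter_up2(y8, x$dims) + layer$params$b
      list(y = list(mat = y, dims = 2L * x$dims),
           cache = list(x = x$mat, id = x$dims))
    },
    inorm = {
      mu <- rowMeans(x$mat)
      xc <- x$mat - mu
      sd <- sqrt(rowMeans(xc * xc) + 1e-5)
      xhat <- xc / sd
      y <- layer$params$g * xhat + layer$params$b
      list(y = list(mat = y, dims = x$dims),
           cache = list(xhat = xhat, sd = sd))
    },
    relu = {
      m <- x$mat > 0
      list(y = list(mat = x$mat * m, dims = x$dims), cache = list(m = m))
    },
    stop("unknown layer type ", layer$type))
}

prim_bwd <- function(layer, cache, dy) {
  switch(layer$type,
    conv3 = {
      dW <- tcrossprod(dy$mat, cache$cols)
      db <- rowSums(dy$mat)
      dcols <- crossprod(layer$params$W, dy$mat)
      dx <- cpp_col2im3d(dcols, cache$dims, 3L, 1L, 1L, layer$cin)
      list(dx = list(mat = dx, dims = cache$dims), grads = list(W = dW, b = db))
    },
    conv1 = {
      dW <- tcrossprod(dy$mat, cache$x)
      db <- rowSums(dy$mat)
      dx <- crossprod(layer$params$W, dy$mat)
      list(dx = list(mat = dx, dims = dy$dims), grads = list(W = dW, b = db))
    },
    down2 = {
      dW <- tcrossprod(dy$mat, cache$g)
      db <- rowSums(dy$mat)
      dg <- crossprod(layer$params$W, dy$mat)
      dx <- cpp_scatter_up2(dg, cache$od)
      list(dx = list(mat = dx, dims = 2L * cache$od),
           grads = list(W = dW, b = db))
    },
    up2 = {
      dy8 <- cpp_gather_down2(dy$mat, cache$id)
      dW <- tcrossprod(dy8, cache$x)
      db <- rowSums(dy$mat)
      dx <- crossprod(layer$params$W, dy8)
      list(dx = list(mat = dx, dims = cache$id), grads = list(W = dW, b = db))
    },
    inorm = {
      g <- layer$params$g
      dxhat <- dy$mat * g
      mh <- rowMeans(dxhat)
      mxh <- rowMeans(dxhat * cache$xhat)
      dx <- (dxhat - mh - cache$xhat * mxh) / cache$sd
      list(dx = list(mat = dx, dims = dy$dims),
           grads = list(g = rowSums(dy$mat * cache$xhat), b = rowSums(dy$mat)))
    },
    relu = {
      list(dx = list(mat = dy$mat * cache$m, dims = dy$dims), grads = NULL)
    })
}

# ---- bottleneck residual block (pre-activation) ---------------------------
# IN -> ReLU -> 1x1 reduce -> IN -> ReLU -> 3x3x3 -> IN -> ReLU -> 1x1 expand,
# added to the (projected) input.

block_bott <- function(cin, cout, norm = TRUE) {
  mid <- max(1L, cout %/% 4L)
  sub <- list(c1 = layer_conv1(cin, mid), c2 = layer_conv3(mid, mid),
              c3 = layer_conv1(mid, cout))
  if (norm) {
    sub$n1 <- layer_inorm(cin); sub$n2 <- layer_inorm(mid)
    sub$n3 <- layer_inorm(mid)
  }
  if (cin != cout) sub$proj <- layer_conv1(cin, cout)
  list(type = "bott", cin = cin, cout = cout, norm = norm, sub = sub)
}

bott_fwd <- function(blk, x) {
  cc <- list()
  h <- x
  run <- function(name, h) {
    r <- prim_fwd(blk$sub[[name]], h)
    cc[[name]] <<- r$cache
    r$y
  }
  relu <- function(h, tag) {
    r <- prim_fwd(list(type = "relu"), h)
    cc[[tag]] <<- r$cache
    r$y
  }
  if (blk$norm) h <- run("n1", h)
  h <- relu(h, "r1")
  h <- run("c1", h)
  if (blk$norm) h <- run("n2", h)
  h <- relu(h, "r2")
  h <- run("c2", h)
  if (blk$norm) h <- run("n3", h)
  h <- relu(h, "r3")
  h <- run("c3", h)
  skip <- if (!is.null(blk$sub$proj)) run("proj", x) else x
  list(y = list(mat = h$mat + skip$mat, dims = x$dims), cache = cc)
}

bott_bwd <- function(blk, cache, dy) {
  grads <- list()
  back <- function(name, d) {
    r <- prim_bwd(blk$sub[[name]], cache[[name]], d)
    if (!is.null(r$grads)) grads[[name]] <<- r$grads
    r$dx
  }
  relu_b <- function(d, tag) {
    prim_bwd(list(type = "relu"), cache[[tag]], d)$dx
  }
  dskip <- dy
  if (!is.null(blk$sub$proj)) dskip <- back("proj", dy)
  d <- back("c3", dy)
  d <- relu_b(d, "r3")
  if (blk$norm) d <- back("n3", d)
  d <- back("c2", d)
  d <- relu_b(d, "r2")
  if (blk$norm) d <- back("n2", d)
  d <- back("c1", d)
  d <- relu_b(d, "r1")
  if (blk$norm) d <- back("n1", d)
  list(dx = list(mat = d$mat + dskip$mat, dims = dy$dims), grads = grads)
}

#' Build a segmentation network
#'
#' Architecture: a 3D input convolution merging the input channels, then per
#' scale a strided down-sampling convolution followed by a bottleneck
#' residual block; the decoder mirrors it with transposed convolutions whose
#' outputs are concatenated with the same-scale encoder features and fused by
#' a residual block; a 1x1x1 convolution aggregates the final feature map
#' into per-class scores. Weights are He-initialised from the current RNG
#' state (seed for reproducibility).
#'
#' @param config A [net_config()].
#' @return A `vwi_model` (layers + config).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "net_config"))
  w0 <- config$base_width
  S <- config$n_scales
  widths <- w0 * 2^(0:S)
  cin <- config$in_channels + if (isTRUE(config$coords)) 3L else 0L
  L <- list(stem = layer_conv3(cin, w0))
  for (s in 1:S) {
    L[[paste0("down", s)]] <- layer_down2(widths[s], widths[s + 1])
    L[[paste0("encblk", s)]] <- block_bott(widths[s + 1], widths[s + 1],
                                           config$norm)
  }
  for (s in S:1) {
    L[[paste0("up", s)]] <- layer_up2(widths[s + 1], widths[s])
    L[[paste0("decblk", s)]] <- block_bott(2L * widths[s], widths[s],
                                           config$norm)
  }
  L$head <- layer_conv1(w0, config$n_classes)
  structure(list(config = config, layers = L), class = "vwi_model")
}

#' @export
print.vwi_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$layers), length, 0L))
  cat(sprintf("<vwi_model  in=%d classes=%d width=%d scales=%d  %d params>\n",
              x$config$in_channels, x$config$n_classes, x$config$base_width,
              x$config$n_scales, np))
  invisible(x)
}

# Forward pass. x: list(mat = C x N, dims). Grid dims must be divisible by
# 2^n_scales (callers pad; see pad_to_multiple).
net_forward <- function(model, x, want_cache = TRUE) {
  S <- model$config$n_scales
  if (any(x$dims %% 2L^S != 0L))
    stop("input grid not divisible by 2^n_scales; pad first")
  L <- model$layers
  caches <- list()
  r <- prim_fwd(L$stem, x); caches$stem <- r$cache
  f <- r$y
  skips <- list(f)
  for (s in 1:S) {
    r <- prim_fwd(L[[paste0("down", s)]], f); caches[[paste0("down", s)]] <- r$cache
    r2 <- bott_fwd(L[[paste0("encblk", s)]], r$y)
    caches[[paste0("encblk", s)]] <- r2$cache
    f <- r2$y
    skips[[s + 1]] <- f
  }
  for (s in S:1) {
    r <- prim_fwd(L[[paste0("up", s)]], f); caches[[paste0("up", s)]] <- r$cache
    cat_in <- list(mat = rbind(r$y$mat, skips[[s]]$mat), dims = r$y$dims)
    r2 <- bott_fwd(L[[paste0("decblk", s)]], cat_in)
    caches[[paste0("decblk", s)]] <- r2$cache
    f <- r2$y
  }
  r <- prim_fwd(L$head, f); caches$head <- r$cache
  if (want_cache) list(out = r$y, caches = caches) else list(out = r$y)
}

# Backward pass; returns grads tree + (unused) input gradient.
net_backward <- function(model, caches, dout) {
  S <- model$config$n_scales
  L <- model$layers
  grads <- list()
  r <- prim_bwd(L$head, caches$head, dout)
  grads$head <- r$grads
  d <- r$dx
  dskips <- vector("list", S + 1)
  for (s in 1:S) {
    r <- bott_bwd(L[[paste0("decblk", s)]], caches[[paste0("decblk", s)]], d)
    grads[[paste0("decblk", s)]] <- r$grads
    cup <- L[[paste0("up", s)]]$cout
    dup <- list(mat = r$dx$mat[seq_len(cup), , drop = FALSE], dims = r$dx$dims)
    dskips[[s]] <- list(mat = r$dx$mat[-seq_len(cup), , drop = FALSE],
                        dims = r$dx$dims)
    r <- prim_bwd(L[[paste0("up", s)]], caches[[paste0("up", s)]], dup)
    grads[[paste0("up", s)]] <- r$grads
    d <- r$dx
  }
  for (s in S:1) {
    if (!is.null(dskips[[s + 1]])) d$mat <- d$mat + dskips[[s + 1]]$mat
    r <- bott_bwd(L[[paste0("encblk", s)]], caches[[paste0("encblk", s)]], d)
    grads[[paste0("encblk", s)]] <- r$grads
    r2 <- prim_bwd(L[[paste0("down", s)]], caches[[paste0("down", s)]], r$dx)
    grads[[paste0("down", s)]] <- r2$grads
    d <- r2$dx
  }
  if (!is.null(dskips[[1]])) d$mat <- d$mat + dskips[[1]]$mat
  r <- prim_bwd(L$stem, caches$stem, d)
  grads$stem <- r$grads
  list(grads = grads, dx = r$dx)
}

# ---- parameter tree utilities ---------------------------------------------

flatten_params <- function(layers, prefix = "") {
  out <- list()
  for (nm in names(layers)) {
    el <- layers[[nm]]
    if (!is.null(el$params)) {
      for (pn in names(el$params))
        out[[paste0(prefix, nm, ".", pn)]] <- el$params[[pn]]
    }
    if (!is.null(el$sub)) {
      out <- c(out, flatten_params(el$sub, paste0(prefix, nm, "/")))
    }
  }
  out
}

assign_params <- function(layers, flat, prefix = "") {
  for (nm in names(layers)) {
    el <- layers[[nm]]
    if (!is.null(el$params)) {
      for (pn in names(el$params)) {
        key <- paste0(prefix, nm, ".", pn)
        if (!is.null(flat[[key]])) layers[[nm]]$params[[pn]] <- flat[[key]]
      }
    }
    if (!is.null(el$sub)) {
      layers[[nm]]$sub <- assign_params(el$sub, flat, paste0(prefix, nm, "/"))
    }
  }
  layers
}

flatten_grads <- function(grads, layers, prefix = "") {
  out <- list()
  for (nm in names(layers)) {
    el <- layers[[nm]]
    if (!is.null(el$params) && !is.null(grads[[nm]])) {
      for (pn in names(el$params))
        out[[paste0(prefix, nm, ".", pn)]] <- grads[[nm]][[pn]]
    }
    if (!is.null(el$sub) && !is.null(grads[[nm]])) {
      out <- c(out, flatten_grads(grads[[nm]], el$sub, paste0(prefix, nm, "/")))
    }
  }
  out
}

# Pad a (C x N, dims) map so dims are divisible by m; constant fill.
pad_to_multiple <- function(x, m, fill = 0) {
  d <- x$dims
  nd <- as.integer(ceiling(d / m) * m)
  if (all(nd == d)) return(list(x = x, orig = d))
  C <- nrow(x$mat)
  big <- array(fill, c(C, nd))
  arr <- array(x$mat, c(C, d))
  big[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  list(x = list(mat = matrix(big, C, prod(nd)), dims = nd), orig = d)
}

crop_from_pad <- function(mat, dims, orig) {
  C <- nrow(mat)
  arr <- array(mat, c(C, dims))
  arr <- arr[, seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]),
             drop = FALSE]
  matrix(arr, C, prod(orig))
}
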