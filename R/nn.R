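# Compact CNN engine: im2col 2D convolutions, ReLU/sigmoid activations,
# nearest-neighbour upsampling, manual reverse-mode gradients and an Adam
# optimizer. Tensors are H x W x C arrays; everything is plain double
# arithmetic so runs are bit-reproducible given a seed and single-threaded
# BLAS. Designed for desk-scale models (tens of thousands of parameters).

# cache of im2col gather indices keyed by geometry
.nn_cache <- new.env(parent = emptyenv())

im2col_indices <- function(h, w, c, k, stride, pad) {
  key <- paste(h, w, c, k, stride, pad, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  oy <- rep(seq.int(0L, by = stride, length.out = ho), times = wo)
  ox <- rep(seq.int(0L, by = stride, length.out = wo), each = ho)
  # columns: kernel row, kernel col, channel (matching weight layout)
  ky <- rep(seq_len(k), times = k * c)
  kx <- rep(rep(seq_len(k), each = k), times = c)
  kc <- rep(seq_len(c), each = k * k)
  idx <- outer(oy, ky, "+") + outer(ox, kx - 1L, "+") * hp +
    matrix((kc - 1L) * hp * wp, length(oy), length(ky), byrow = TRUE)
  out <- list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
  .nn_cache[[key]] <- out
  out
}

pad_tensor <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  out
}

#' Create a convolution layer
#'
#' 2D convolution with a square kernel, "same"-style zero padding
#' (`pad = (k-1)/2`) and optional stride. Weights use He-scaled Gaussian
#' initialization from the current RNG stream.
#'
#' @param in_ch,out_ch Channel counts.
#' @param k Kernel edge (odd).
#' @param stride Stride (1 or 2).
#' @param activation `"linear"`, `"relu"` or `"sigmoid"`.
#' @return Layer object (list).
#' @keywords internal
nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L,
                    activation = "linear") {
  sd <- sqrt(2 / (k * k * in_ch))
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = (as.integer(k) - 1L) %/% 2L,
       in_ch = in_ch, out_ch = out_ch, activation = activation,
       W = matrix(stats::rnorm(k * k * in_ch * out_ch, 0, sd),
                  k * k * in_ch, out_ch),
       b = numeric(out_ch))
}

nn_upsample <- function(factor = 2L) {
  list(type = "upsample", factor = as.integer(factor))
}

layer_forward <- function(layer, x) {
  if (layer$type == "upsample") {
    f <- layer$factor
    d <- dim(x)
    y <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
           drop = FALSE]
    return(list(y = y, cache = d))
  }
  d <- dim(x)
  ii <- im2col_indices(d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
  xp <- pad_tensor(x, layer$pad)
  xcol <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  z <- xcol %*% layer$W
  z <- sweep(z, 2, layer$b, "+")
  a <- switch(layer$activation,
              linear = z,
              relu = pmax(z, 0),
              lrelu = pmax(z, 0) + 0.1 * pmin(z, 0),
              # logits clamped so saturated units keep a nonzero gradient
              sigmoid = 1 / (1 + exp(-pmin(pmax(z, -30), 30))))
  y <- array(a, dim = c(ii$ho, ii$wo, layer$out_ch))
  list(y = y, cache = list(xcol = xcol, z = z, a = a, ii = ii, din = d))
}

layer_backward <- function(layer, dy, cache) {
  if (layer$type == "upsample") {
    f <- layer$factor
    d <- cache
    dd <- dim(dy)
    dx <- array(0, dim = d)
    for (i in seq_len(f)) {
      for (j in seq_len(f)) {
        dx <- dx + dy[seq.int(i, dd[1], by = f), seq.int(j, dd[2], by = f), ,
                      drop = FALSE]
      }
    }
    return(list(dx = dx, dW = NULL, db = NULL))
  }
  ii <- cache$ii
  dmat <- matrix(dy, nrow(ii$idx), layer$out_ch)
  da <- switch(layer$activation,
               linear = dmat,
               relu = dmat * (cache$z > 0),
               lrelu = dmat * ifelse(cache$z > 0, 1, 0.1),
               sigmoid = dmat * cache$a * (1 - cache$a))
  dW <- crossprod(cache$xcol, da)
  db <- colSums(da)
  dxcol <- tcrossprod(da, layer$W)
  # col2im: one strided block-add per kernel offset
  k <- layer$k; cin <- cache$din[3]; stride <- layer$stride
  dxp <- array(0, dim = c(ii$hp, ii$wp, cin))
  for (kx in seq_len(k)) {
    for (ky in seq_len(k)) {
      cols <- ky + (kx - 1L) * k + (seq_len(cin) - 1L) * k * k
      blk <- array(dxcol[, cols], dim = c(ii$ho, ii$wo, cin))
      rows <- seq.int(ky, by = stride, length.out = ii$ho)
      ccols <- seq.int(kx, by = stride, length.out = ii$wo)
      dxp[rows, ccols, ] <- dxp[rows, ccols, , drop = FALSE] + blk
    }
  }
  pad <- layer$pad
  dx <- dxp[(pad + 1L):(pad + cache$din[1]),
            (pad + 1L):(pad + cache$din[2]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

stack_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x)
    x <- fw$y
    caches[[i]] <- fw$cache
  }
  list(y = x, caches = caches)
}

stack_backward <- function(layers, dy, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], dy, caches[[i]])
    grads[[i]] <- list(dW = bw$dW, db = bw$db)
    dy <- bw$dx
  }
  list(dx = dy, grads = grads)
}

stack_param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, 0L))
}

# Adam state and update for a named list of layer stacks
adam_init <- function(parts) {
  st <- list(t = 0L, m = list(), v = list())
  for (p in names(parts)) {
    st$m[[p]] <- lapply(parts[[p]], function(l) {
      if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0)
    })
    st$v[[p]] <- st$m[[p]]
  }
  st
}

adam_step <- function(parts, grads, state, lr, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in names(parts)) {
    if (!trainable[[p]]) next
    for (i in seq_along(parts[[p]])) {
      g <- grads[[p]][[i]]
      if (is.null(g$dW)) next
      for (nm in c("W", "b")) {
        gv <- if (nm == "W") g$dW else g$db
        state$m[[p]][[i]][[nm]] <- beta1 * state$m[[p]][[i]][[nm]] +
          (1 - beta1) * gv
        state$v[[p]][[i]][[nm]] <- beta2 * state$v[[p]][[i]][[nm]] +
          (1 - beta2) * gv^2
        mhat <- state$m[[p]][[i]][[nm]] / bc1
        vhat <- state$v[[p]][[i]][[nm]] / bc2
        parts[[p]][[i]][[nm]] <- parts[[p]][[i]][[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(parts = parts, state = state)
}

param_checksum <- function(layers) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0 else sum(l$W) + sum(l$b)
  }, 0))
}
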