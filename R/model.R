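#' Detector model configuration
#'
#' @param input_size Input edge length in pixels (must be divisible by 4 for
#'   the bundled backbone; default 384).
#' @param backbone Backbone name. This build bundles `test_tiny`, a compact
#'   strided CNN (under 200k parameters) used for all desk-scale runs; the
#'   full-scale `efficientnet_v2s` and `vit` compositions are recognised
#'   names but not bundled.
#' @param neck_channels,head_channels Channel widths of the neck and of the
#'   head upsampling trunk.
#' @param top Output head: `"detect"` (1-channel sigmoid centroid heatmap +
#'   2-channel sigmoid size maps) or `"pretrain_rgb"` (3-channel sigmoid
#'   reconstruction).
#' @param freeze `"none"`, `"backbone"` or `"backbone_and_neck"`.
#' @param shared_context Use one shared parameter set for the previous- and
#'   next-slice context branches (default FALSE: per-branch parameters).
#' @return List of class `model_config`.
#' @export
model_config <- function(input_size = 384L,
                         backbone = c("test_tiny", "efficientnet_v2s", "vit"),
                         neck_channels = 32L, head_channels = 16L,
                         top = c("detect", "pretrain_rgb"),
                         freeze = c("none", "backbone", "backbone_and_neck"),
                         shared_context = FALSE) {
  backbone <- match.arg(backbone)
  top <- match.arg(top)
  freeze <- match.arg(freeze)
  stopifnot(input_size %% 4L == 0L)
  structure(list(input_size = as.integer(input_size), backbone = backbone,
                 neck_channels = as.integer(neck_channels),
                 head_channels = as.integer(head_channels),
                 top = top, freeze = freeze,
                 shared_context = shared_context),
            class = "model_config")
}

context_branch <- function() {
  list(nn_conv(1L, 10L, k = 3L, activation = "linear"),
       nn_conv(10L, 1L, k = 1L, activation = "linear"))
}

make_top <- function(top, in_ch) {
  if (top == "detect") {
    heat <- nn_conv(in_ch, 1L, k = 1L, activation = "sigmoid")
    # negative bias prior: the mostly-background heatmap starts near its
    # base rate, so early gradients focus on cells instead of shrinking the
    # head weights (standard practice for centroid-heatmap detectors)
    heat$b[] <- -2
    list(heat = list(heat),
         size = list(nn_conv(in_ch, 2L, k = 1L, activation = "sigmoid")))
  } else {
    list(rgb = list(nn_conv(in_ch, 3L, k = 1L, activation = "sigmoid")))
  }
}

#' Build a centroid detector model
#'
#' Assembles the prepended slice-context block, the backbone, an
#' attention-augmenting neck (convolutional at the bundled scale), the fully
#' convolutional upsampling head trunk and the configured top. Initial
#' parameters are drawn from the given seed, so two builds with the same
#' seed are identical.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return Model object (list of parameter stacks plus config).
#' @export
build_model <- function(cfg, seed = 1L) {
  if (cfg$backbone != "test_tiny") {
    stop("backbone '", cfg$backbone, "' is not bundled; use 'test_tiny'")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nc <- cfg$neck_channels; hc <- cfg$head_channels
  parts <- list(
    context_prev = context_branch(),
    context_next = NULL,
    backbone = list(nn_conv(3L, 16L, k = 3L, stride = 2L, activation = "lrelu"),
                    nn_conv(16L, 32L, k = 3L, stride = 2L, activation = "lrelu")),
    neck = list(nn_conv(32L, nc, k = 3L, activation = "lrelu"),
                nn_conv(nc, nc, k = 1L, activation = "lrelu")),
    head_trunk = list(nn_upsample(2L),
                      nn_conv(nc, hc, k = 3L, activation = "lrelu"),
                      nn_upsample(2L),
                      nn_conv(hc, 8L, k = 3L, activation = "lrelu")),
    top = make_top(cfg$top, 8L))
  parts$context_next <- if (cfg$shared_context) parts$context_prev
                        else context_branch()
  structure(list(cfg = cfg, parts = parts), class = "cell_model")
}

context_forward <- function(model, s_prev, s_cur, s_next) {
  to3d <- function(m) array(m, dim = c(dim(m), 1L))
  fp <- stack_forward(model$parts$context_prev, to3d(s_prev))
  fn <- stack_forward(model$parts$context_next, to3d(s_next))
  u1 <- fp$y[, , 1] * s_cur + s_cur
  u3 <- fn$y[, , 1] * s_cur + s_cur
  ch1 <- 1 / (1 + exp(-u1))
  ch3 <- 1 / (1 + exp(-u3))
  y <- array(0, dim = c(dim(s_cur), 3L))
  y[, , 1] <- ch1; y[, , 2] <- s_cur; y[, , 3] <- ch3
  list(y = y, cache = list(fp = fp, fn = fn, s_cur = s_cur,
                           ch1 = ch1, ch3 = ch3))
}

#' Slice-context block
#'
#' Fuses a slice with its two z-neighbours: each neighbour passes through a
#' 3x3 convolution with 10 filters and a 1x1 depth-fusing convolution, the
#' result is merged with the current slice by a multiply-accumulate and
#' squashed with a sigmoid. Channel 1 carries previous-slice context,
#' channel 2 the unchanged current slice, channel 3 next-slice context. For
#' 2D inputs all three slices are the same image and the block produces
#' three learned views of it.
#'
#' @param s_prev,s_cur,s_next H x W matrices in [0,1].
#' @param model A [build_model()] result holding the branch parameters.
#' @return H x W x 3 array.
#' @export
context_block <- function(s_prev, s_cur, s_next, model) {
  stopifnot(all(dim(s_prev) == dim(s_cur)), all(dim(s_next) == dim(s_cur)))
  context_forward(model, s_prev, s_cur, s_next)$y
}

#' Model forward pass
#'
#' @param model A `cell_model`.
#' @param s_cur Current slice (H x W in [0,1]).
#' @param s_prev,s_next Neighbouring slices; default to `s_cur` (2D input).
#' @param with_cache Keep intermediate activations for a backward pass.
#' @return For a detect top, list with `heatmap` (H x W) and `size` (H x W x
#'   2: width, height); for a pretrain top, `rgb` (H x W x 3). With
#'   `with_cache = TRUE`, a `cache` entry is added.
#' @export
model_forward <- function(model, s_cur, s_prev = s_cur, s_next = s_cur,
                          with_cache = FALSE) {
  cf <- context_forward(model, s_prev, s_cur, s_next)
  fb <- stack_forward(model$parts$backbone, cf$y)
  fn <- stack_forward(model$parts$neck, fb$y)
  ft <- stack_forward(model$parts$head_trunk, fn$y)
  tops <- lapply(model$parts$top, function(st) stack_forward(st, ft$y))
  out <- if (model$cfg$top == "detect") {
    list(heatmap = tops$heat$y[, , 1], size = tops$size$y)
  } else {
    list(rgb = tops$rgb$y)
  }
  if (with_cache) {
    out$cache <- list(cf = cf, fb = fb, fn = fn, ft = ft, tops = tops)
  }
  out
}

# backward pass; d_top is a named list of gradients w.r.t. each top output
# (arrays shaped like the outputs). Returns per-part gradients.
model_backward <- function(model, cache, d_top) {
  grads <- list()
  dtrunk <- 0
  for (nm in names(model$parts$top)) {
    bw <- stack_backward(model$parts$top[[nm]], d_top[[nm]],
                         cache$tops[[nm]]$caches)
    grads$top[[nm]] <- bw$grads
    dtrunk <- dtrunk + bw$dx
  }
  bw <- stack_backward(model$parts$head_trunk, dtrunk, cache$ft$caches)
  grads$head_trunk <- bw$grads
  bw <- stack_backward(model$parts$neck, bw$dx, cache$fn$caches)
  grads$neck <- bw$grads
  bw <- stack_backward(model$parts$backbone, bw$dx, cache$fb$caches)
  grads$backbone <- bw$grads
  dctx <- bw$dx
  cc <- cache$cf$cache
  du1 <- dctx[, , 1] * cc$ch1 * (1 - cc$ch1)
  du3 <- dctx[, , 3] * cc$ch3 * (1 - cc$ch3)
  df1 <- array(du1 * cc$s_cur, dim = c(dim(cc$s_cur), 1L))
  df3 <- array(du3 * cc$s_cur, dim = c(dim(cc$s_cur), 1L))
  grads$context_prev <- stack_backward(model$parts$context_prev, df1,
                                       cc$fp$caches)$grads
  grads$context_next <- stack_backward(model$parts$context_next, df3,
                                       cc$fn$caches)$grads
  grads
}

#' Swap the model top
#'
#' Replaces the final output layers for a new task format while preserving
#' every other parameter bit-exactly — the mechanism for moving between
#' pre-training (3-channel reconstruction) and detection (heatmap + sizes).
#' The new top is initialized from `seed`.
#'
#' @param model A `cell_model`.
#' @param new_top `"detect"` or `"pretrain_rgb"`.
#' @param seed Seed for the new top's initialization.
#' @return The model with the new top.
#' @export
swap_top <- function(model, new_top = c("detect", "pretrain_rgb"),
                     seed = 1L) {
  new_top <- match.arg(new_top)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  model$parts$top <- make_top(new_top, 8L)
  model$cfg$top <- new_top
  model
}

#' Set the freeze mode
#'
#' `"none"` trains everything (fine-tuning); `"backbone"` freezes the
#' backbone (backbone evaluation); `"backbone_and_neck"` freezes backbone
#' and neck (head evaluation). Frozen parts are excluded from optimizer
#' updates. The context block and heads remain trainable in every mode.
#'
#' @param model A `cell_model`.
#' @param mode Freeze mode.
#' @return The model with the mode recorded.
#' @export
set_freeze <- function(model, mode = c("none", "backbone",
                                       "backbone_and_neck")) {
  model$cfg$freeze <- match.arg(mode)
  model
}

trainable_parts <- function(model) {
  fr <- model$cfg$freeze
  list(context_prev = TRUE, context_next = TRUE,
       backbone = fr == "none",
       neck = fr %in% c("none", "backbone"),
       head_trunk = TRUE, top = TRUE)
}

#' Count model parameters
#'
#' @param model A `cell_model`.
#' @param part One of `"total"`, `"backbone"`, `"neck"`, `"heads"` (trunk
#'   plus top) or `"context_block"` (both branches).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, part = c("total", "backbone", "neck",
                                             "heads", "context_block")) {
  part <- match.arg(part)
  p <- model$parts
  ctx <- if (model$cfg$shared_context) {
    stack_param_count(p$context_prev)
  } else {
    stack_param_count(p$context_prev) + stack_param_count(p$context_next)
  }
  counts <- c(backbone = stack_param_count(p$backbone),
              neck = stack_param_count(p$neck),
              heads = stack_param_count(p$head_trunk) +
                sum(vapply(p$top, stack_param_count, 0L)),
              context_block = ctx)
  if (part == "total") sum(counts) else unname(counts[part])
}

#' Parameter checksums per model part
#'
#' Sums of all weights and biases per part; used to verify freeze and
#' top-swap contracts.
#'
#' @param model A `cell_model`.
#' @return Named numeric vector.
#' @export
model_checksums <- function(model) {
  p <- model$parts
  c(context_prev = param_checksum(p$context_prev),
    context_next = param_checksum(p$context_next),
    backbone = param_checksum(p$backbone),
    neck = param_checksum(p$neck),
    head_trunk = param_checksum(p$head_trunk),
    top = sum(vapply(p$top, param_checksum, 0)))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON files holding a format version, the configuration
#' and every parameter array, so they survive as plain text.
#'
#' @param model A `cell_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  ser_stack <- function(layers) lapply(layers, function(l) {
    out <- l[setdiff(names(l), c("W", "b"))]
    if (!is.null(l$W)) {
      out$W <- as.vector(l$W); out$Wdim <- dim(l$W); out$b <- l$b
    }
    out
  })
  obj <- list(format_version = 1L, cfg = unclass(model$cfg),
              parts = list(
                context_prev = ser_stack(model$parts$context_prev),
                context_next = ser_stack(model$parts$context_next),
                backbone = ser_stack(model$parts$backbone),
                neck = ser_stack(model$parts$neck),
                head_trunk = ser_stack(model$parts$head_trunk),
                top = lapply(model$parts$top, ser_stack)))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored `cell_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported checkpoint format")
  }
  de_layer <- function(l) {
    out <- list(type = l$type)
    if (out$type == "upsample") {
      out$factor <- as.integer(l$factor)
      return(out)
    }
    out$k <- as.integer(l$k); out$stride <- as.integer(l$stride)
    out$pad <- as.integer(l$pad)
    out$in_ch <- as.integer(l$in_ch); out$out_ch <- as.integer(l$out_ch)
    out$activation <- l$activation
    wd <- as.integer(unlist(l$Wdim))
    out$W <- matrix(as.numeric(unlist(l$W)), wd[1], wd[2])
    out$b <- as.numeric(unlist(l$b))
    out
  }
  de_stack <- function(layers) lapply(layers, de_layer)
  cfg <- model_config(input_size = as.integer(obj$cfg$input_size),
                      backbone = obj$cfg$backbone,
                      neck_channels = as.integer(obj$cfg$neck_channels),
                      head_channels = as.integer(obj$cfg$head_channels),
                      top = obj$cfg$top, freeze = obj$cfg$freeze,
                      shared_context = isTRUE(obj$cfg$shared_context))
  parts <- list(context_prev = de_stack(obj$parts$context_prev),
                context_next = de_stack(obj$parts$context_next),
                backbone = de_stack(obj$parts$backbone),
                neck = de_stack(obj$parts$neck),
                head_trunk = de_stack(obj$parts$head_trunk),
                top = lapply(obj$parts$top, de_stack))
  structure(list(cfg = cfg, parts = parts), class = "cell_model")
}
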