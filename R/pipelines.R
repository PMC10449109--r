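#' Run configuration
#'
#' Bundles the task, model configuration, masking and colormap choices,
#' optimizer settings and data source for a pre-training, training or
#' evaluation run. Optimizer defaults follow the reference setup: Adam with
#' initial learning rate 1e-4, reduced on plateaus by a factor of 10 down to
#' 1e-6. Default epoch counts are 75 for pseudo-color pre-training, 50 for
#' plain autoencoding and 50 for detection training; desk-scale smoke runs
#' override these.
#'
#' @param task `"pretrain"`, `"train"` or `"eval"`.
#' @param model A [model_config()].
#' @param mask A [mask_spec()] or NULL for unmasked input.
#' @param colormap Colormap name for the pre-training target
#'   (`"gray_identity"` expresses plain autoencoding).
#' @param lr,plateau_factor,lr_min,plateau_patience Adam learning-rate
#'   schedule: reduce-on-plateau by `plateau_factor` after
#'   `plateau_patience` epochs without improvement, never below `lr_min`.
#' @param epochs Number of epochs; default depends on task/colormap.
#' @param batch_size Samples per optimizer step (default 8 at 384 input,
#'   32 at 64).
#' @param seed Integer master seed for the run.
#' @param data List describing the data source: either
#'   `list(scene = scene_spec(...), n_images = N)` for synthetic scenes or
#'   `list(tiff_dir = path)` for a directory of TIFFs.
#' @return List of class `run_config`.
#' @export
run_config <- function(task = c("pretrain", "train", "eval"),
                       model = model_config(input_size = 64L),
                       mask = NULL,
                       colormap = "nipy_spectral",
                       lr = 1e-4, plateau_factor = 10, lr_min = 1e-6,
                       plateau_patience = 5L,
                       epochs = NULL,
                       batch_size = if (model$input_size >= 384L) 8L else 32L,
                       seed = 1L,
                       data = list(scene = scene_spec(image_size =
                                     rep(model$input_size, 2L)),
                                   n_images = 50L)) {
  task <- match.arg(task)
  if (is.null(epochs)) {
    epochs <- if (task == "pretrain" && colormap != "gray_identity") 75L
              else 50L
  }
  stopifnot(epochs >= 1L, lr_min <= lr)
  structure(list(task = task, model = model, mask = mask,
                 colormap = colormap,
                 optimizer = list(algo = "adam", lr = lr,
                                  plateau_factor = plateau_factor,
                                  lr_min = lr_min,
                                  plateau_patience = as.integer(plateau_patience)),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), data = data),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()]; nested `model`,
#'   `mask` and `data.scene` blocks are passed to their constructors.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- if (is.null(y$model)) model_config(input_size = 64L)
           else do.call(model_config, y$model)
  mask <- if (is.null(y$mask)) NULL else do.call(mask_spec, y$mask)
  data <- y$data
  if (!is.null(data$scene)) data$scene <- do.call(scene_spec, data$scene)
  args <- y[setdiff(names(y), c("model", "mask", "data"))]
  args$model <- model; args$mask <- mask
  if (!is.null(data)) args$data <- data
  do.call(run_config, args)
}

# --- dataset assembly ------------------------------------------------------

load_dataset <- function(cfg) {
  d <- cfg$data
  if (!is.null(d$tiff_dir)) {
    paths <- sort(list.files(d$tiff_dir, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (!length(paths)) stop("no TIFF images found in ", d$tiff_dir)
    return(lapply(paths, function(p) {
      list(image = unclass(preprocess(read_gray(p))), annotations = NULL)
    }))
  }
  n <- d$n_images %||% 50L
  lapply(seq_len(n), function(i) {
    sp <- d$scene
    sp$seed <- cfg$seed * 100000L + i
    sc <- generate_scene(sp)
    list(image = unclass(preprocess(sc$image)), annotations = sc$annotations)
  })
}

# --- optimizer plumbing ----------------------------------------------------

flatten_parts <- function(model) {
  p <- model$parts
  out <- list(context_prev = p$context_prev, context_next = p$context_next,
              backbone = p$backbone, neck = p$neck,
              head_trunk = p$head_trunk)
  for (nm in names(p$top)) out[[paste0("top_", nm)]] <- p$top[[nm]]
  out
}

unflatten_parts <- function(model, flat) {
  model$parts$context_prev <- flat$context_prev
  model$parts$context_next <- flat$context_next
  model$parts$backbone <- flat$backbone
  model$parts$neck <- flat$neck
  model$parts$head_trunk <- flat$head_trunk
  for (nm in names(model$parts$top)) {
    model$parts$top[[nm]] <- flat[[paste0("top_", nm)]]
  }
  model
}

flatten_grads <- function(grads) {
  out <- grads[c("context_prev", "context_next", "backbone", "neck",
                 "head_trunk")]
  for (nm in names(grads$top)) out[[paste0("top_", nm)]] <- grads$top[[nm]]
  out
}

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (p in names(g)) {
    for (i in seq_along(g[[p]])) {
      if (is.null(g[[p]][[i]]$dW)) next
      acc[[p]][[i]]$dW <- acc[[p]][[i]]$dW + g[[p]][[i]]$dW
      acc[[p]][[i]]$db <- acc[[p]][[i]]$db + g[[p]][[i]]$db
    }
  }
  acc
}

scale_grads <- function(g, s) {
  for (p in names(g)) {
    for (i in seq_along(g[[p]])) {
      if (is.null(g[[p]][[i]]$dW)) next
      g[[p]][[i]]$dW <- g[[p]][[i]]$dW * s
      g[[p]][[i]]$db <- g[[p]][[i]]$db * s
    }
  }
  g
}

flat_trainable <- function(model) {
  tr <- trainable_parts(model)
  out <- list(context_prev = tr$context_prev,
              context_next = tr$context_next,
              backbone = tr$backbone, neck = tr$neck,
              head_trunk = tr$head_trunk)
  for (nm in names(model$parts$top)) out[[paste0("top_", nm)]] <- tr$top
  out
}

plateau_update <- function(sched, loss) {
  if (loss < sched$best - 1e-12) {
    sched$best <- loss
    sched$wait <- 0L
  } else {
    sched$wait <- sched$wait + 1L
    if (sched$wait >= sched$patience) {
      sched$lr <- max(sched$lr / sched$factor, sched$lr_min)
      sched$wait <- 0L
    }
  }
  sched
}

huber_grad <- function(y, y_hat) {
  d <- y_hat - y
  ifelse(abs(d) <= 1, d, sign(d)) / length(y)
}

# --- pipelines -------------------------------------------------------------

#' Self-supervised pre-training: pseudo-colorize masked cells
#'
#' Per sample: preprocess, optionally corrupt the input with a padded or
#' MAE-style mask (fresh mask each epoch), run the model with its 3-channel
#' reconstruction top and minimize the pixel-wise MSE against the
#' pseudo-colorized, *unmasked* image. With `colormap = "gray_identity"` and
#' `mask = NULL` this is plain autoencoding.
#'
#' @param cfg A [run_config()] with `task = "pretrain"`.
#' @param checkpoint Optional path to save the final model.
#' @return List of class `run_history`: `history` (per-epoch data.frame with
#'   loss, ssim, lr), the trained `model` and the frozen `config` snapshot.
#' @export
pretrain <- function(cfg, checkpoint = NULL) {
  stopifnot(cfg$task == "pretrain")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  mcfg <- cfg$model; mcfg$top <- "pretrain_rgb"
  model <- build_model(mcfg, seed = cfg$seed)
  ds <- load_dataset(cfg)
  targets <- lapply(ds, function(s) {
    apply_colormap(s$image, colormap_lut(cfg$colormap))
  })
  opt <- adam_init(flatten_parts(model))
  sched <- list(lr = cfg$optimizer$lr, factor = cfg$optimizer$plateau_factor,
                lr_min = cfg$optimizer$lr_min,
                patience = cfg$optimizer$plateau_patience,
                best = Inf, wait = 0L)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    losses <- numeric(length(ds)); ssims <- numeric(length(ds))
    acc <- NULL; nb <- 0L
    for (i in seq_along(ds)) {
      x <- ds[[i]]$image
      if (!is.null(cfg$mask)) {
        msk <- cfg$mask
        msk$image_size <- dim(x)
        msk$seed <- cfg$seed * 1000L + ep * length(ds) + i
        x <- apply_mask(x, make_mask(msk))
      }
      fw <- model_forward(model, x, with_cache = TRUE)
      tgt <- targets[[i]]
      losses[i] <- mse_reconstruction(fw$rgb, tgt)
      ssims[i] <- ssim(fw$rgb, tgt, L = 1)
      d_top <- list(rgb = 2 * (fw$rgb - tgt) / length(tgt))
      g <- flatten_grads(model_backward(model, fw$cache, d_top))
      acc <- acc_grads(acc, g); nb <- nb + 1L
      if (nb == cfg$batch_size || i == length(ds)) {
        step <- adam_step(flatten_parts(model), scale_grads(acc, 1 / nb),
                          opt, sched$lr, flat_trainable(model))
        model <- unflatten_parts(model, step$parts)
        opt <- step$state
        acc <- NULL; nb <- 0L
      }
    }
    sched <- plateau_update(sched, mean(losses))
    hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                             ssim = mean(ssims), lr = sched$lr)
  }
  res <- structure(list(history = do.call(rbind, hist), model = model,
                        config = cfg), class = "run_history")
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  res
}

#' Detection training with freeze modes
#'
#' Optimizes the weighted sum of three per-head Huber losses (heatmap 1,
#' height 1/2, width 1/2) on centroid-heatmap and size-map targets encoded
#' from the ground-truth annotations. The freeze mode of the model config
#' selects the training procedure: `none` is fine-tuning,
#' `backbone_and_neck` is head evaluation, `backbone` is backbone
#' evaluation.
#'
#' @param cfg A [run_config()] with `task = "train"`.
#' @param init_model Optional pre-trained `cell_model` (its top is swapped
#'   to the detection format; all other weights are kept) or a checkpoint
#'   path.
#' @param checkpoint Optional path to save the final model.
#' @return `run_history` with per-epoch loss components, training mIoU and
#'   learning rate.
#' @export
train_detect <- function(cfg, init_model = NULL, checkpoint = NULL) {
  stopifnot(cfg$task == "train")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  if (is.character(init_model)) init_model <- load_checkpoint(init_model)
  model <- if (is.null(init_model)) {
    mcfg <- cfg$model; mcfg$top <- "detect"
    build_model(mcfg, seed = cfg$seed)
  } else {
    m <- init_model
    if (m$cfg$top != "detect") m <- swap_top(m, "detect", seed = cfg$seed)
    m
  }
  model <- set_freeze(model, cfg$model$freeze)
  ds <- load_dataset(cfg)
  if (any(vapply(ds, function(s) is.null(s$annotations), TRUE))) {
    stop("detection training requires annotated data")
  }
  targets <- lapply(ds, function(s) encode_targets(s$annotations, dim(s$image)))
  opt <- adam_init(flatten_parts(model))
  sched <- list(lr = cfg$optimizer$lr, factor = cfg$optimizer$plateau_factor,
                lr_min = cfg$optimizer$lr_min,
                patience = cfg$optimizer$plateau_patience,
                best = Inf, wait = 0L)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lh <- numeric(length(ds)); lwd <- numeric(length(ds))
    lht <- numeric(length(ds)); mious <- numeric(length(ds))
    acc <- NULL; nb <- 0L
    for (i in seq_along(ds)) {
      fw <- model_forward(model, ds[[i]]$image, with_cache = TRUE)
      tg <- targets[[i]]
      lh[i] <- huber(tg$heatmap, fw$heatmap)
      lwd[i] <- huber(tg$width_map, fw$size[, , 1])
      lht[i] <- huber(tg$height_map, fw$size[, , 2])
      mious[i] <- miou(fw$heatmap, tg$heatmap)
      dheat <- array(huber_grad(tg$heatmap, fw$heatmap),
                     dim = c(dim(fw$heatmap), 1L))
      dsize <- array(0, dim = dim(fw$size))
      dsize[, , 1] <- 0.5 * huber_grad(tg$width_map, fw$size[, , 1])
      dsize[, , 2] <- 0.5 * huber_grad(tg$height_map, fw$size[, , 2])
      g <- flatten_grads(model_backward(model, fw$cache,
                                        list(heat = dheat, size = dsize)))
      acc <- acc_grads(acc, g); nb <- nb + 1L
      if (nb == cfg$batch_size || i == length(ds)) {
        step <- adam_step(flatten_parts(model), scale_grads(acc, 1 / nb),
                          opt, sched$lr, flat_trainable(model))
        model <- unflatten_parts(model, step$parts)
        opt <- step$state
        acc <- NULL; nb <- 0L
      }
    }
    ltot <- total_loss(mean(lh), mean(lht), mean(lwd))
    sched <- plateau_update(sched, ltot)
    hist[[ep]] <- data.frame(epoch = ep, l_heatmap = mean(lh),
                             l_height = mean(lht), l_width = mean(lwd),
                             l_total = ltot, miou = mean(mious),
                             lr = sched$lr)
  }
  res <- structure(list(history = do.call(rbind, hist), model = model,
                        config = cfg), class = "run_history")
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  res
}

#' Evaluate a detector on annotated data
#'
#' Runs the model on every image, decodes detections from the predicted
#' maps, computes the mean thresholded mIoU against encoded ground-truth
#' heatmaps and optionally writes COCO ground-truth and results JSON for an
#' external AP evaluator.
#'
#' @param model A `cell_model` with a detect top, or a checkpoint path.
#' @param dataset List of samples, each `list(image=, annotations=)`, e.g.
#'   from [generate_scene()] results; must be non-empty with annotations.
#' @param coco_dir Optional directory for `ground_truth.json` and
#'   `results.json`.
#' @return List with mean `miou`, per-image `miou_per_image` and a
#'   `detections` list of data.frames.
#' @export
evaluate_detector <- function(model, dataset, coco_dir = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!length(dataset)) stop("empty dataset")
  if (any(vapply(dataset, function(s) is.null(s$annotations), TRUE))) {
    stop("evaluation requires ground-truth annotations")
  }
  mious <- numeric(length(dataset))
  dets <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    fw <- model_forward(model, s$image)
    tg_heat <- encode_heatmap(s$annotations, dim(s$image))
    mious[i] <- miou(fw$heatmap, tg_heat)
    dets[[i]] <- decode_detections(fw$heatmap, fw$size[, , 1],
                                   fw$size[, , 2], dim(s$image))
  }
  if (!is.null(coco_dir)) {
    dir.create(coco_dir, showWarnings = FALSE, recursive = TRUE)
    export_coco_gt(lapply(dataset, `[[`, "annotations"),
                   lapply(dataset, function(s) dim(s$image)),
                   file.path(coco_dir, "ground_truth.json"))
    export_coco_results(dets, file.path(coco_dir, "results.json"))
  }
  list(miou = mean(mious), miou_per_image = mious, detections = dets)
}
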