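# strip class/attribute decoration from an image matrix
bare <- function(x) { attributes(x) <- list(dim = dim(x)); x }

# Independent reference implementations used as oracles in tests.

# brute-force 3x3 median with symmetric reflection padding
ref_median3x3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  xp <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- stats::median(xp[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

# match each annotation to its nearest detection; returns per-cell errors
match_detections <- function(det, ann) {
  stopifnot(nrow(ann) > 0)
  t(vapply(seq_len(nrow(ann)), function(j) {
    d2 <- (det$centroid_x - ann$centroid_x[j])^2 +
      (det$centroid_y - ann$centroid_y[j])^2
    i <- which.min(d2)
    c(centroid = sqrt(d2[i]),
      width = abs(det$width[i] - ann$width[j]),
      height = abs(det$height[i] - ann$height[j]))
  }, c(centroid = 0, width = 0, height = 0)))
}

# longest run of TRUE along every row and column of a logical matrix
max_true_run <- function(m) {
  runmax <- function(v) {
    r <- rle(v)
    w <- r$lengths[r$values]
    if (length(w)) max(w) else 0L
  }
  # insert a FALSE between columns/rows so runs cannot wrap
  byrow <- runmax(as.vector(rbind(t(m), FALSE)))
  bycol <- runmax(as.vector(rbind(m, FALSE)))
  max(byrow, bycol)
}

smoke_train_config <- function(seed, n_images = 100L,
                               freeze = "none", epochs = 5L) {
  run_config(task = "train",
             model = model_config(input_size = 64L, freeze = freeze),
             lr = 1e-3, epochs = epochs, batch_size = 4L, seed = seed,
             data = list(scene = smoke_scene_spec(), n_images = n_images))
}

smoke_pretrain_config <- function(seed, n_images = 50L, epochs = 2L,
                                  mask = mask_spec("padded", seed = 1L),
                                  colormap = "nipy_spectral") {
  run_config(task = "pretrain", model = model_config(input_size = 64L),
             mask = mask, colormap = colormap,
             lr = 1e-3, epochs = epochs, batch_size = 4L, seed = seed,
             data = list(scene = smoke_scene_spec(), n_images = n_images))
}
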