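#' Synthetic fluorescence scene specification
#'
#' Parameters of the seeded generator of fluorescence-like images: a dark
#' noisy background with bright elliptical cells of varying size and
#' per-cell intensity. Defaults emulate simulated-nuclei fluorescence
#' imagery at 384 x 384: 5-15 cells per frame, semi-axes 5-15 px, cell
#' intensities 0.55-1, background level 0.05, Gaussian read noise with
#' sigma 0.02 and a minimum centroid separation that keeps nuclei disjoint.
#'
#' @param image_size `c(H, W)`.
#' @param n_cells Integer count or `c(min, max)` range.
#' @param axis_range `c(min, max)` ellipse semi-axes in pixels.
#' @param intensity_range `c(lo, hi)` cell intensities in (0, 1].
#' @param background_level Background intensity in [0, 1).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param min_separation Minimum distance between cell centroids (pixels).
#' @param edge_sigma Gaussian blur sigma (pixels) softening cell borders.
#' @param seed Integer seed.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(384L, 384L),
                       n_cells = c(5L, 15L),
                       axis_range = c(5, 15),
                       intensity_range = c(0.55, 1),
                       background_level = 0.05,
                       noise_sigma = 0.02,
                       min_separation = 40,
                       edge_sigma = 1,
                       seed = 1L) {
  stopifnot(axis_range[1] <= axis_range[2],
            intensity_range[1] <= intensity_range[2],
            min_separation >= 0, background_level >= 0, background_level < 1)
  structure(list(image_size = as.integer(image_size), n_cells = n_cells,
                 axis_range = axis_range, intensity_range = intensity_range,
                 background_level = background_level,
                 noise_sigma = noise_sigma, min_separation = min_separation,
                 edge_sigma = edge_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# small separable Gaussian blur, reflected edges
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(m, r) m[c(rev(seq_len(r)), seq_len(nrow(m)),
                                    nrow(m) - seq_len(r) + 1L), , drop = FALSE]
  conv_rows <- function(m) {
    mp <- pad_reflect(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[(i):(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(x))))
}

#' Generate a synthetic fluorescence scene
#'
#' Draws `n_cells` filled ellipses with rejection-sampled centroids (pairwise
#' distance at least `min_separation`), per-cell intensity and axes, softens
#' cell borders with a small Gaussian blur, adds background level and
#' Gaussian noise and clips to [0,1]. The exact instance mask and bounding
#' box annotations are returned alongside the image, mutually consistent
#' with [masks_to_boxes()].
#'
#' @param spec A [scene_spec()].
#' @return List of class `synthetic_scene` with `image` (H x W in [0,1]),
#'   `annotations` (data.frame like [masks_to_boxes()]) and `instance_mask`
#'   (integer H x W).
#' @export
generate_scene <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- if (length(spec$n_cells) == 2L) {
    sample(spec$n_cells[1]:spec$n_cells[2], 1L)
  } else as.integer(spec$n_cells)

  amax <- spec$axis_range[2]
  cents <- matrix(numeric(), 0, 2)
  tries <- 0L
  while (nrow(cents) < n) {
    tries <- tries + 1L
    if (tries > 1000L * max(n, 1L)) {
      stop("rejection sampling failed; lower the cell density or separation")
    }
    cand <- c(stats::runif(1, amax, w - 1 - amax),
              stats::runif(1, amax, h - 1 - amax))
    if (nrow(cents) == 0L ||
        all(sqrt(rowSums(t(t(cents) - cand)^2)) >= spec$min_separation)) {
      cents <- rbind(cents, cand)
    }
  }

  img <- matrix(0, h, w)
  mask <- matrix(0L, h, w)
  for (i in seq_len(min(n, nrow(cents)))) {
    a <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    b <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    inten <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
    ell <- ellipse_mask(h, w, cents[i, 1], cents[i, 2], a, b)
    img[ell] <- pmax(img[ell], inten)
    mask[ell] <- i
  }
  # annotations from the realized instance mask, so the triple is consistent
  annotations <- masks_to_boxes(mask)
  img <- gauss_blur(img, spec$edge_sigma)
  img <- img + spec$background_level +
    matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, annotations = annotations,
                 instance_mask = mask, spec = spec),
            class = "synthetic_scene")
}

#' Generate a synthetic 3D stack of ellipsoidal cells
#'
#' Cells are 3D ellipsoids; slice z shows the ellipsoid's elliptical
#' cross-section, whose in-plane semi-axes shrink by the factor
#' `sqrt(1 - (dz / c)^2)` away from the cell's central slice — so 2D cell
#' size decreases from the middle of the volume toward its borders, and
#' slices that miss the ellipsoid are empty.
#'
#' @param spec A [scene_spec()]; in-plane axes come from `axis_range`.
#' @param depth Number of z-slices (at least 3).
#' @param z_axis_frac Ellipsoid z semi-axis as a fraction of `depth / 2`
#'   (default 0.8).
#' @return List of class `synthetic_stack` with `volume` (H x W x Z),
#'   `annotations` (list of per-slice data.frames) and `instance_masks`
#'   (H x W x Z integer array).
#' @export
generate_stack <- function(spec, depth, z_axis_frac = 0.8) {
  stopifnot(depth >= 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- if (length(spec$n_cells) == 2L) {
    sample(spec$n_cells[1]:spec$n_cells[2], 1L)
  } else as.integer(spec$n_cells)

  amax <- spec$axis_range[2]
  cents <- matrix(numeric(), 0, 2)
  tries <- 0L
  while (nrow(cents) < n) {
    tries <- tries + 1L
    if (tries > 1000L * max(n, 1L)) {
      stop("rejection sampling failed; lower the cell density or separation")
    }
    cand <- c(stats::runif(1, amax, w - 1 - amax),
              stats::runif(1, amax, h - 1 - amax))
    if (nrow(cents) == 0L ||
        all(sqrt(rowSums(t(t(cents) - cand)^2)) >= spec$min_separation)) {
      cents <- rbind(cents, cand)
    }
  }
  cells <- lapply(seq_len(n), function(i) {
    list(cx = cents[i, 1], cy = cents[i, 2],
         cz = (depth - 1) / 2,
         a = stats::runif(1, spec$axis_range[1], spec$axis_range[2]),
         b = stats::runif(1, spec$axis_range[1], spec$axis_range[2]),
         cc = z_axis_frac * (depth - 1) / 2,
         inten = stats::runif(1, spec$intensity_range[1],
                              spec$intensity_range[2]))
  })
  vol <- array(0, dim = c(h, w, depth))
  masks <- array(0L, dim = c(h, w, depth))
  noise <- array(stats::rnorm(h * w * depth, 0, spec$noise_sigma),
                 dim = c(h, w, depth))
  anns <- vector("list", depth)
  for (z in seq_len(depth)) {
    img <- matrix(0, h, w)
    m <- matrix(0L, h, w)
    for (i in seq_len(n)) {
      cl <- cells[[i]]
      dz <- (z - 1) - cl$cz
      if (abs(dz) >= cl$cc) next
      shrink <- sqrt(1 - (dz / cl$cc)^2)
      az <- cl$a * shrink; bz <- cl$b * shrink
      if (az < 0.5 || bz < 0.5) next
      ell <- ellipse_mask(h, w, cl$cx, cl$cy, az, bz)
      if (!any(ell)) next
      img[ell] <- pmax(img[ell], cl$inten)
      m[ell] <- i
    }
    anns[[z]] <- masks_to_boxes(m)
    img <- gauss_blur(img, spec$edge_sigma)
    vol[, , z] <- pmin(pmax(img + spec$background_level + noise[, , z], 0), 1)
    masks[, , z] <- m
  }
  structure(list(volume = vol, annotations = anns, instance_masks = masks,
                 spec = spec),
            class = "synthetic_stack")
}

#' Geometric augmentation of an image and its annotations
#'
#' Applies a sequence of geometric operations, transforming the annotations
#' consistently with the pixels. Supported: horizontal/vertical flip,
#' 90-degree counter-clockwise rotation and random crop retaining at least
#' `crop_min` of each side (cells whose centroid leaves the crop are
#' dropped).
#'
#' @param image H x W matrix.
#' @param annotations Annotation data.frame (0-based centroids).
#' @param ops Character vector from `c("hflip", "vflip", "rot90", "crop")`,
#'   applied in order.
#' @param crop_min Minimum retained fraction of each side (default 0.9).
#' @return List with transformed `image` and `annotations`.
#' @export
augment <- function(image, annotations, ops, crop_min = 0.9) {
  img <- unclass(image)
  ann <- annotations
  for (op in ops) {
    h <- nrow(img); w <- ncol(img)
    if (op == "hflip") {
      img <- img[, w:1, drop = FALSE]
      if (nrow(ann)) ann$centroid_x <- (w - 1) - ann$centroid_x
    } else if (op == "vflip") {
      img <- img[h:1, , drop = FALSE]
      if (nrow(ann)) ann$centroid_y <- (h - 1) - ann$centroid_y
    } else if (op == "rot90") {
      # counter-clockwise: new[y', x'] = old[y = x', x = W-1-y'] (0-based)
      img <- t(img)[w:1, , drop = FALSE]
      if (nrow(ann)) {
        newy <- (w - 1) - ann$centroid_x
        newx <- ann$centroid_y
        tmpw <- ann$width
        ann$centroid_x <- newx; ann$centroid_y <- newy
        ann$width <- ann$height; ann$height <- tmpw
      }
    } else if (op == "crop") {
      nh <- as.integer(ceiling(crop_min * h) +
                         floor(stats::runif(1) * (h - ceiling(crop_min * h) + 1)))
      nw <- as.integer(ceiling(crop_min * w) +
                         floor(stats::runif(1) * (w - ceiling(crop_min * w) + 1)))
      y0 <- as.integer(floor(stats::runif(1) * (h - nh + 1)))
      x0 <- as.integer(floor(stats::runif(1) * (w - nw + 1)))
      img <- img[(y0 + 1):(y0 + nh), (x0 + 1):(x0 + nw), drop = FALSE]
      if (nrow(ann)) {
        ann$centroid_x <- ann$centroid_x - x0
        ann$centroid_y <- ann$centroid_y - y0
        keep <- ann$centroid_x >= 0 & ann$centroid_x <= nw - 1 &
          ann$centroid_y >= 0 & ann$centroid_y <= nh - 1
        ann <- ann[keep, , drop = FALSE]
      }
    } else {
      stop("unknown augmentation op: ", op)
    }
  }
  rownames(ann) <- NULL
  list(image = img, annotations = ann)
}

#' Desk-scale synthetic scene configuration
#'
#' The 64 x 64 counterpart of the default 384 x 384 scene: 2-5 cells with
#' semi-axes 4-8 px and proportionally reduced separation. Used by the
#' package's smoke-scale training examples and tests.
#'
#' @param seed Integer seed.
#' @return A [scene_spec()].
#' @export
smoke_scene_spec <- function(seed = 1L) {
  scene_spec(image_size = c(64L, 64L), n_cells = c(2L, 5L),
             axis_range = c(4, 8), intensity_range = c(0.55, 1),
             background_level = 0.05, noise_sigma = 0.02,
             min_separation = 18, edge_sigma = 1, seed = seed)
}
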