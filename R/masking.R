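#' Masking specification
#'
#' Describes either the padded patch-masking scheme (small patches, each
#' surrounded by guaranteed-unmasked padding, masked independently with a
#' fixed probability) or MAE-style masking (non-overlapping patches, a fixed
#' fraction masked without replacement).
#'
#' Padded defaults follow the reference geometry at 384 x 384: 12 px patches,
#' padding of a quarter patch (3 px, shared between neighbours so the tile
#' stride is 15 px) and masking probability 0.5. MAE defaults are 16 px
#' patches at 224 x 224 with a 0.75 mask ratio.
#'
#' @param scheme `"padded"` or `"mae"`.
#' @param image_size `c(H, W)` in pixels.
#' @param patch_size Patch edge in pixels.
#' @param padding Padding in pixels (padded scheme only).
#' @param mask_prob Per-patch masking probability (padded scheme).
#' @param mae_mask_ratio Fraction of patches masked (MAE scheme).
#' @param seed Integer seed recorded with the spec and used by [make_mask()].
#' @return List of class `mask_spec`.
#' @export
mask_spec <- function(scheme = c("padded", "mae"),
                      image_size = if (scheme == "padded") c(384L, 384L) else c(224L, 224L),
                      patch_size = if (scheme == "padded") 12L else 16L,
                      padding = patch_size %/% 4L,
                      mask_prob = 0.5,
                      mae_mask_ratio = 0.75,
                      seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(patch_size >= 1L, padding >= 0L,
            mask_prob >= 0, mask_prob <= 1,
            mae_mask_ratio >= 0, mae_mask_ratio <= 1,
            length(image_size) == 2L, all(image_size >= 1L))
  structure(list(scheme = scheme, image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 padding = as.integer(padding),
                 mask_prob = mask_prob, mae_mask_ratio = mae_mask_ratio,
                 seed = as.integer(seed)),
            class = "mask_spec")
}

new_mask_grid <- function(mask, spec) {
  structure(list(mask = mask, spec = spec, masked_fraction = mean(mask)),
            class = "mask_grid")
}

#' Generate a mask from a specification
#'
#' Dispatches to [padded_mask()] or [mae_mask()] according to the scheme and
#' seeds the generator from `spec$seed`, so the same spec always produces a
#' bit-identical mask.
#'
#' @param spec A [mask_spec()].
#' @return `mask_grid`: list with the H x W logical `mask` (TRUE = masked),
#'   the generating `spec` and the exact `masked_fraction`.
#' @export
make_mask <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  if (spec$scheme == "padded") padded_mask(spec) else mae_mask(spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Padded patch mask
#'
#' The image is tiled on a stride of `patch_size + padding` (the padding is
#' shared between neighbouring tiles). Within each tile the top-left
#' `patch_size` x `patch_size` region is masked independently with
#' probability `mask_prob`; partial tiles at the right/bottom border mask
#' only their in-bounds portion. Masked regions of distinct tiles are
#' therefore separated by at least `padding` pixels along both axes, which
#' prevents large connected masked areas.
#'
#' Uses the current RNG state; call via [make_mask()] for seeded generation.
#'
#' @param spec A [mask_spec()] with `scheme = "padded"`.
#' @return A `mask_grid`.
#' @export
padded_mask <- function(spec) {
  stopifnot(spec$scheme == "padded")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  stride <- spec$patch_size + spec$padding
  if (stride > min(h, w)) stop("tile stride exceeds image size")
  ys <- seq.int(1L, h, by = stride)
  xs <- seq.int(1L, w, by = stride)
  draw <- matrix(stats::runif(length(ys) * length(xs)) < spec$mask_prob,
                 nrow = length(ys))
  m <- matrix(FALSE, h, w)
  for (i in seq_along(ys)) {
    for (j in seq_along(xs)) {
      if (draw[i, j]) {
        y1 <- min(ys[i] + spec$patch_size - 1L, h)
        x1 <- min(xs[j] + spec$patch_size - 1L, w)
        m[ys[i]:y1, xs[j]:x1] <- TRUE
      }
    }
  }
  new_mask_grid(m, spec)
}

#' MAE-style patch mask
#'
#' Divides the image into non-overlapping `patch_size` x `patch_size`
#' patches (the grid must tile the image exactly) and masks exactly
#' `round(ratio * n_patches)` patches chosen uniformly without replacement.
#'
#' @param spec A [mask_spec()] with `scheme = "mae"`.
#' @return A `mask_grid`; when the grid tiles the image the masked fraction
#'   equals the patch ratio exactly.
#' @export
mae_mask <- function(spec) {
  stopifnot(spec$scheme == "mae")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  p <- spec$patch_size
  if (h %% p != 0L || w %% p != 0L) {
    stop("MAE grid must tile the image: size not divisible by patch_size")
  }
  nh <- h %/% p; nw <- w %/% p
  n <- nh * nw
  k <- round(spec$mae_mask_ratio * n)
  chosen <- if (k > 0) sample.int(n, k) else integer()
  m <- matrix(FALSE, h, w)
  for (id in chosen) {
    i <- (id - 1L) %/% nw; j <- (id - 1L) %% nw
    m[(i * p + 1L):((i + 1L) * p), (j * p + 1L):((j + 1L) * p)] <- TRUE
  }
  new_mask_grid(m, spec)
}

#' Apply a mask to an image
#'
#' Masked pixels are set to the fill value (0 by default, matching the
#' pre-training corruption); unmasked pixels are returned bit-identical.
#' `fill = "random01"` instead fills each masked patch region with a common
#' value drawn from the discrete uniform distribution on {0, 1}; with this
#' option pixel fills are drawn per masked pixel run at generation time via
#' the grid's spec seed.
#'
#' @param img H x W matrix.
#' @param grid A `mask_grid` of matching size.
#' @param fill `"zero"` (default) or `"random01"`.
#' @return Matrix of the same shape.
#' @export
apply_mask <- function(img, grid, fill = c("zero", "random01")) {
  fill <- match.arg(fill)
  x <- unclass(img)
  if (!all(dim(x) == dim(grid$mask))) stop("image/mask shape mismatch")
  if (fill == "zero") {
    x[grid$mask] <- 0
  } else {
    # one common U{0,1} value per connected masked patch region
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(grid$spec$seed + 1L)
    lab <- label_blobs(grid$mask)
    n <- max(lab)
    if (n > 0L) {
      vals <- sample(c(0, 1), n, replace = TRUE)
      x[grid$mask] <- vals[lab[grid$mask]]
    }
  }
  x
}

#' Scale a patch size to another image resolution
#'
#' Returns the patch size at `new_size` that covers the same image fraction
#' as `base_patch` at `base_size`: `round(base_patch * new_size / base_size)`.
#' For example a 16 px patch at 224 px corresponds to a 27 px patch at
#' 384 px.
#'
#' @param base_patch,base_size,new_size Positive pixel counts.
#' @return Integer patch size.
#' @export
equivalent_patch_size <- function(base_patch, base_size, new_size) {
  stopifnot(base_patch > 0, base_size > 0, new_size > 0)
  as.integer(round(base_patch * new_size / base_size))
}

#' Expected masked fraction of a padded mask
#'
#' Enumerates the tile grid and sums each tile's in-bounds patch area,
#' returning `mask_prob * total_patch_area / (H * W)` — the analytic
#' expectation of the masked fraction under the padded scheme.
#'
#' @param spec A [mask_spec()] with `scheme = "padded"`.
#' @return Expected fraction in [0,1].
#' @export
expected_padded_fraction <- function(spec) {
  stopifnot(spec$scheme == "padded")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  stride <- spec$patch_size + spec$padding
  ys <- seq.int(1L, h, by = stride)
  xs <- seq.int(1L, w, by = stride)
  hy <- pmin(ys + spec$patch_size - 1L, h) - ys + 1L
  wx <- pmin(xs + spec$patch_size - 1L, w) - xs + 1L
  spec$mask_prob * sum(outer(hy, wx)) / (h * w)
}

#' Calibrated masking probability for a target coverage
#'
#' Inverts [expected_padded_fraction()]: returns the `mask_prob` whose
#' expected coverage equals `target_fraction` for the given geometry.
#'
#' @param spec A padded [mask_spec()] (its `mask_prob` is ignored).
#' @param target_fraction Desired expected masked fraction.
#' @return Probability in [0,1].
#' @export
calibrated_prob <- function(spec, target_fraction) {
  base <- expected_padded_fraction(`[[<-`(spec, "mask_prob", 1))
  p <- target_fraction / base
  if (p > 1) stop("target coverage unattainable for this geometry")
  p
}
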