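#' Colormap lookup tables
#'
#' The package ships four 256-entry RGB lookup tables precomputed from the
#' standard published control points of widely used colormaps, plus a
#' `gray_identity` LUT that maps index i to (i/255, i/255, i/255):
#'
#' * `rainbow` — a spectral (visible-light) colormap,
#' * `seismic` — a diverging blue/red colormap,
#' * `nipy_spectral` — a pseudo-spectral colormap extending a spectral map by
#'   prepending black at low and appending gray at high intensities; the
#'   package default for pseudo-colorization,
#' * `viridis` — a perceptually uniform sequential colormap,
#' * `gray_identity` — identity grayscale, expressing plain autoencoding in
#'   the same code path.
#'
#' @param name Colormap name.
#' @return A 256 x 3 numeric matrix with columns R, G, B, all values in
#'   [0,1]; class `colormap_lut`, with the name in attribute `name`.
#' @export
colormap_lut <- function(name = c("nipy_spectral", "rainbow", "seismic",
                                  "viridis", "gray_identity")) {
  name <- match.arg(name)
  if (name == "gray_identity") {
    v <- (0:255) / 255
    lut <- cbind(R = v, G = v, B = v)
  } else {
    path <- system.file("extdata", "luts", paste0(name, ".csv"),
                        package = "pseudocell", mustWork = TRUE)
    tab <- utils::read.csv(path)
    lut <- as.matrix(tab[, c("R", "G", "B")])
  }
  stopifnot(nrow(lut) == 256L, all(lut >= 0), all(lut <= 1))
  structure(lut, name = name, class = c("colormap_lut", "matrix", "array"))
}

#' Apply a colormap lookup table to a grayscale image
#'
#' Each pixel value v in [0,1] is quantized to the nearest of 256 LUT indices
#' (`round(v * 255)`) and replaced by that entry's RGB triple. The mapping is
#' deterministic; no interpolation is performed, so targets are
#' bit-reproducible.
#'
#' @param img H x W matrix with values in [0,1].
#' @param lut A [colormap_lut()].
#' @return H x W x 3 array, channels in [0,1].
#' @export
apply_colormap <- function(img, lut) {
  x <- unclass(img)
  stopifnot(is.matrix(x))
  if (any(x < 0 | x > 1)) {
    stop("image values outside [0,1]; preprocess() the image first")
  }
  idx <- as.integer(round(x * 255)) + 1L
  rgb <- array(0, dim = c(nrow(x), ncol(x), 3L))
  rgb[, , 1] <- lut[idx, 1]
  rgb[, , 2] <- lut[idx, 2]
  rgb[, , 3] <- lut[idx, 3]
  rgb
}

#' Perceived brightness of RGB values (HSP model)
#'
#' Computes the perceived brightness B_p = sqrt(0.299 R^2 + 0.587 G^2 +
#' 0.114 B^2) of one or more RGB triples. The channel weights are those of
#' the HSP color model, which weights green most heavily to match human
#' luminance sensitivity.
#'
#' @param rgb Numeric vector of length 3, or an n x 3 matrix of triples, all
#'   channels in [0,1].
#' @return Scalar or length-n vector in [0,1].
#' @export
perceived_brightness <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3L, byrow = FALSE)
  stopifnot(ncol(rgb) == 3L)
  sqrt(0.299 * rgb[, 1]^2 + 0.587 * rgb[, 2]^2 + 0.114 * rgb[, 3]^2)
}

#' Perceived-brightness profile of a colormap
#'
#' Evaluates [perceived_brightness()] at each of the 256 LUT entries, giving
#' the grayscale curve that characterizes how a colormap distributes
#' brightness over intensity levels.
#'
#' @param lut A [colormap_lut()].
#' @return Numeric vector of length 256.
#' @export
brightness_profile <- function(lut) {
  perceived_brightness(unclass(lut))
}

#' Pseudo-colorize a cell image
#'
#' The pre-training target generator: preprocesses the image if needed
#' (median filter + min-max scaling, skipped when values already lie in
#' [0,1]) and applies the named colormap. The default, `nipy_spectral`, maps
#' low intensities primarily to bluish colors, medium to greenish and high to
#' reddish, so the three RGB channels approximate a coarse semantic
#' segmentation of cell topology.
#'
#' @param img H x W matrix (raw or preprocessed).
#' @param colormap Colormap name; see [colormap_lut()].
#' @return H x W x 3 array in [0,1].
#' @export
pseudocolor_target <- function(img, colormap = "nipy_spectral") {
  x <- unclass(img)
  stopifnot(is.matrix(x))
  if (any(x < 0 | x > 1)) x <- unclass(preprocess(x))
  apply_colormap(x, colormap_lut(colormap))
}
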