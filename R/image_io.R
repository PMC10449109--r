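#' Read a grayscale TIFF image or stack
#'
#' Reads a single-page TIFF as a 2D intensity matrix and a multi-page TIFF as
#' a 3D stack. Intensities are returned as floats on their native integer
#' scale (0..255 for 8-bit, 0..65535 for 16-bit); no rescaling is applied so
#' the read is lossless. The originating bit depth is recorded in the
#' `bit_depth` attribute.
#'
#' @param path Path to a TIFF file.
#' @return For a single page, an H x W numeric matrix (class
#'   `gray_image`). For multiple pages, an H x W x Z numeric array (class
#'   `cell_volume`) with `z = 1` the first acquired slice.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) {
        p <- p[, , 1L]
      } else {
        stop("expected single-channel grayscale TIFF, page ", i,
             " has ", dim(p)[3], " channels")
      }
    }
    storage.mode(p) <- "double"
    p
  })
  bps <- attr(pages[[1]], "bits.per.sample")
  bit_depth <- if (is.null(bps)) "float" else as.character(bps)
  if (length(mats) == 1L) {
    gray_image(mats[[1]], bit_depth = bit_depth)
  } else {
    dims <- unique(vapply(mats, function(m) paste(dim(m), collapse = "x"), ""))
    if (length(dims) != 1L) stop("stack pages differ in size")
    vol <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    structure(vol, bit_depth = bit_depth, class = "cell_volume")
  }
}

#' Construct a grayscale image
#'
#' @param pixels Numeric H x W matrix of non-negative intensities.
#' @param bit_depth Origin bit depth: "8", "16" or "float".
#' @return The matrix with class `gray_image` and a `bit_depth` attribute.
#' @export
gray_image <- function(pixels, bit_depth = "float") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  structure(pixels, bit_depth = bit_depth,
            class = c("gray_image", class(pixels)))
}

#' Write a grayscale image or RGB array as TIFF
#'
#' @param img H x W matrix in [0,1] or H x W x 3 array in [0,1].
#' @param path Output path.
#' @export
write_gray <- function(img, path) {
  x <- unclass(img)
  attributes(x) <- list(dim = dim(x))
  tiff::writeTIFF(x, path)
  invisible(path)
}

# 3x3 median via a 19-comparator sorting network over the 9 reflected
# neighbourhood shifts; vectorised over all pixels at once.
median3x3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  # reflection padding (edge rows/cols mirrored without repeating the edge
  # pixel would be "reflect"; here we use symmetric reflection including the
  # edge, the common default for small medical-image kernels)
  xp <- x[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  s <- function(dy, dx) xp[(1L + dy):(h + dy), (1L + dx):(w + dx)]
  p <- list(s(0, 0), s(0, 1), s(0, 2),
            s(1, 0), s(1, 1), s(1, 2),
            s(2, 0), s(2, 1), s(2, 2))
  swap <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's median-of-9 network
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5)
  swap(5, 3)
  p[[5]]
}

#' Preprocess a microscopy image
#'
#' Applies a 3x3 median filter (reflection padding at the borders) followed by
#' min-max scaling to [0,1]. If the filtered image has zero range the result
#' is all zeros.
#'
#' @param img H x W numeric matrix, H and W at least 3.
#' @return `gray_image` with values in [0,1].
#' @export
preprocess <- function(img) {
  x <- unclass(img)
  stopifnot(is.matrix(x), nrow(x) >= 3L, ncol(x) >= 3L)
  x <- median3x3(x)
  rng <- range(x)
  if (rng[2] > rng[1]) {
    x <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    x[] <- 0
  }
  gray_image(x, bit_depth = attr(img, "bit_depth") %||% "float")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an instance-label image to bounding-box annotations
#'
#' Each nonzero label yields one annotation: the tight axis-aligned bounding
#' box of its pixels, with `width = x_max - x_min + 1`,
#' `height = y_max - y_min + 1` and the centroid at the geometric center of
#' that box. Coordinates are 0-based with x = column and y = row.
#'
#' @param label_image Integer-valued H x W matrix; 0 is background.
#' @return data.frame with columns `label_id`, `centroid_x`, `centroid_y`,
#'   `width`, `height`, ordered by ascending `label_id`. Empty masks give a
#'   zero-row frame.
#' @export
masks_to_boxes <- function(label_image) {
  x <- unclass(label_image)
  stopifnot(is.matrix(x))
  labs <- sort(unique(as.vector(x)))
  labs <- labs[labs != 0]
  empty <- data.frame(label_id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), width = numeric(),
                      height = numeric())
  if (length(labs) == 0L) return(empty)
  rows <- lapply(labs, function(l) {
    idx <- which(x == l, arr.ind = TRUE)
    y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1]) - 1L
    x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2]) - 1L
    data.frame(label_id = as.integer(l),
               centroid_x = (x0 + x1) / 2,
               centroid_y = (y0 + y1) / 2,
               width = x1 - x0 + 1,
               height = y1 - y0 + 1)
  })
  do.call(rbind, rows)
}

#' Cut a 3D stack into slice triplets
#'
#' Yields one (previous, current, next) triplet per z-slice, replicating the
#' edge slices (at `z = 1` the previous slice is the slice itself, likewise at
#' `z = Z`). A 2D image is treated as a single-slice stack, giving one triplet
#' with all three entries equal.
#'
#' @param vol H x W x Z array, or an H x W matrix.
#' @return List of length Z; each element a list with entries `prev`, `cur`,
#'   `nxt` (H x W matrices).
#' @export
slice_triplets <- function(vol) {
  v <- unclass(vol)
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  stopifnot(length(dim(v)) == 3L)
  z <- dim(v)[3]
  lapply(seq_len(z), function(i) {
    list(prev = v[, , max(i - 1L, 1L)],
         cur  = v[, , i],
         nxt  = v[, , min(i + 1L, z)])
  })
}

#' Export annotations as COCO detection ground truth
#'
#' Writes a standard COCO ground-truth JSON (images / annotations with
#' `[x, y, w, h]` boxes / one "cell" category) for one or more images.
#'
#' @param annotations_list List of annotation data.frames (one per image) as
#'   produced by [masks_to_boxes()] or [generate_scene()].
#' @param image_sizes List of `c(H, W)` per image.
#' @param path Output JSON path.
#' @export
export_coco_gt <- function(annotations_list, image_sizes, path) {
  stopifnot(length(annotations_list) == length(image_sizes))
  images <- lapply(seq_along(image_sizes), function(i) {
    list(id = i, height = image_sizes[[i]][1], width = image_sizes[[i]][2],
         file_name = sprintf("image_%04d.tif", i))
  })
  ann_id <- 0L
  anns <- list()
  for (i in seq_along(annotations_list)) {
    a <- annotations_list[[i]]
    if (nrow(a) == 0L) next
    for (j in seq_len(nrow(a))) {
      ann_id <- ann_id + 1L
      x0 <- a$centroid_x[j] - a$width[j] / 2
      y0 <- a$centroid_y[j] - a$height[j] / 2
      anns[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = 1L,
        bbox = c(x0, y0, a$width[j], a$height[j]),
        area = a$width[j] * a$height[j], iscrowd = 0L)
    }
  }
  obj <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "cell")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
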