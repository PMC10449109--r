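#' Box-filter kernel size for a cell
#'
#' The smoothing kernel is scaled to the cell: `kx = w %/% 1.5`,
#' `ky = h %/% 1.5` (floor division), each clamped to at least 1 and forced
#' odd by adding 1 when even so the filter is centered and the heatmap peak
#' stays on the centroid.
#'
#' @param width,height Cell dimensions in pixels.
#' @return Integer vector `c(kx, ky)`.
#' @export
box_kernel <- function(width, height) {
  stopifnot(width >= 1, height >= 1)
  k <- c(max(1L, as.integer(width %/% 1.5)),
         max(1L, as.integer(height %/% 1.5)))
  k + (k %% 2L == 0L)
}

# normalized box filter (mean filter) with zero padding, separable cumsums
box_filter <- function(x, kx, ky) {
  h <- nrow(x); w <- ncol(x)
  rx <- (kx - 1L) %/% 2L; ry <- (ky - 1L) %/% 2L
  # rows (y axis, kernel ky), then columns (x axis, kernel kx)
  cs <- rbind(0, apply(x, 2, cumsum))
  up <- pmin(seq_len(h) + ry, h) + 1L
  lo <- pmax(seq_len(h) - ry - 1L, 0L) + 1L
  x <- (cs[up, , drop = FALSE] - cs[lo, , drop = FALSE]) / ky
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  up <- pmin(seq_len(w) + rx, w) + 1L
  lo <- pmax(seq_len(w) - rx - 1L, 0L) + 1L
  (cs[, up, drop = FALSE] - cs[, lo, drop = FALSE]) / kx
}

# filled axis-aligned ellipse as a logical matrix
ellipse_mask <- function(h, w, cx, cy, a, b) {
  xs <- matrix((0:(w - 1L) - cx) / a, h, w, byrow = TRUE)
  ys <- matrix((0:(h - 1L) - cy) / b, h, w)
  xs^2 + ys^2 <= 1
}

#' Encode annotations as a centroid heatmap
#'
#' Each cell is approximated by a filled axis-aligned ellipse (semi-axes
#' w/2 and h/2, value 1) on a zero map and smoothed with a normalized box
#' filter of size [box_kernel()]. Contributions of overlapping cells combine
#' by per-pixel maximum, so values stay in [0,1] and each well-separated cell
#' keeps an identical, translation-equivariant profile.
#'
#' @param annotations data.frame with `centroid_x`, `centroid_y`, `width`,
#'   `height` (0-based pixel coordinates).
#' @param image_size `c(H, W)`.
#' @return H x W heatmap in [0,1]; all zeros for empty annotations.
#' @export
encode_heatmap <- function(annotations, image_size) {
  h <- image_size[1]; w <- image_size[2]
  out <- matrix(0, h, w)
  if (is.null(annotations) || nrow(annotations) == 0L) return(out)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    ell <- ellipse_mask(h, w, a$centroid_x, a$centroid_y,
                        a$width / 2, a$height / 2) * 1
    k <- box_kernel(a$width, a$height)
    out <- pmax(out, box_filter(ell, k[1], k[2]))
  }
  pmin(out, 1)
}

#' Encode annotations as width and height maps
#'
#' For each cell, a centered rectangle of half the cell size (w/2 x h/2)
#' carries the constant values `w / W` and `h / H` — the cell dimensions
#' relative to the image size. Where rectangles of different cells overlap,
#' the larger cell (by area) wins.
#'
#' @inheritParams encode_heatmap
#' @return List with `width_map` and `height_map`, H x W each, values in
#'   [0,1].
#' @export
encode_size_maps <- function(annotations, image_size) {
  h <- image_size[1]; w <- image_size[2]
  wm <- matrix(0, h, w); hm <- matrix(0, h, w)
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(list(width_map = wm, height_map = hm))
  }
  ord <- order(annotations$width * annotations$height)  # larger drawn last
  for (i in ord) {
    a <- annotations[i, ]
    x0 <- max(0L, as.integer(round(a$centroid_x - a$width / 4)))
    x1 <- min(w - 1L, as.integer(round(a$centroid_x + a$width / 4)))
    y0 <- max(0L, as.integer(round(a$centroid_y - a$height / 4)))
    y1 <- min(h - 1L, as.integer(round(a$centroid_y + a$height / 4)))
    wm[(y0:y1) + 1L, (x0:x1) + 1L] <- a$width / w
    hm[(y0:y1) + 1L, (x0:x1) + 1L] <- a$height / h
  }
  list(width_map = wm, height_map = hm)
}

#' Threshold a heatmap into a binary blob map
#'
#' Strict comparison: a pixel is foreground iff its value exceeds 0.75; a
#' value of exactly 0.75 is background.
#'
#' @param heatmap H x W map in [0,1].
#' @param threshold Decision threshold (default 0.75).
#' @return Logical H x W matrix.
#' @export
threshold_blobs <- function(heatmap, threshold = 0.75) {
  heatmap > threshold
}

#' Label 8-connected components of a binary map
#'
#' Breadth-first labeling over foreground pixels with 8-connectivity.
#' Labels are assigned in raster-scan order of each component's first pixel.
#'
#' @param binary Logical H x W matrix.
#' @return Integer H x W matrix; 0 = background, components numbered from 1.
#' @export
label_blobs <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  fg <- which(binary)
  for (start in fg) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      cy <- (cur - 1L) %% h + 1L
      cx <- (cur - 1L) %/% h + 1L
      for (d in 1:8) {
        dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)[d]
        dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)[d]
        ny <- cy + dy; nx <- cx + dx
        ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
        if (!any(ok)) next
        ni <- (nx[ok] - 1L) * h + ny[ok]
        ni <- ni[binary[ni] & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- nxt
          queue <- c(queue, ni)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Centroid of a blob from raw image moments
#'
#' Computes the raw moments M00, M10, M01 of a set of blob pixels with unit
#' weight and returns the centroid `(M10/M00, M01/M00)` = (mean column,
#' mean row), 0-based.
#'
#' @param xs,ys 0-based pixel coordinates of the blob (x = column, y = row).
#' @return Numeric `c(cx, cy)`.
#' @export
blob_centroid <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) > 0)
  m00 <- length(xs)
  c(sum(xs) / m00, sum(ys) / m00)
}

#' Decode heatmap and size maps into detections
#'
#' Thresholds the heatmap (strict > 0.75), labels 8-connected blobs, drops
#' components smaller than `min_area` pixels, computes each blob's centroid
#' from image moments and looks up the cell dimensions in the size maps at
#' the rounded centroid pixel. Boxes are emitted as top-left corner plus
#' width and height; the score is the heatmap value at the rounded centroid.
#'
#' @param heatmap,width_map,height_map H x W maps sharing one shape.
#' @param image_size `c(H, W)` used to rescale relative sizes to pixels;
#'   defaults to the map shape.
#' @param threshold Heatmap threshold (default 0.75).
#' @param min_area Minimum blob area in pixels (default 4).
#' @return data.frame with `x_topleft`, `y_topleft`, `width`, `height`,
#'   `centroid_x`, `centroid_y`, `score`; zero rows when nothing exceeds the
#'   threshold.
#' @export
decode_detections <- function(heatmap, width_map, height_map,
                              image_size = dim(heatmap),
                              threshold = 0.75, min_area = 4L) {
  stopifnot(all(dim(heatmap) == dim(width_map)),
            all(dim(heatmap) == dim(height_map)))
  h <- image_size[1]; w <- image_size[2]
  lab <- label_blobs(threshold_blobs(heatmap, threshold))
  empty <- data.frame(x_topleft = numeric(), y_topleft = numeric(),
                      width = numeric(), height = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      score = numeric())
  n <- max(lab)
  if (n == 0L) return(empty)
  rows <- list()
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    cen <- blob_centroid(idx[, 2] - 1, idx[, 1] - 1)
    ry <- as.integer(round(cen[2])) + 1L
    rx <- as.integer(round(cen[1])) + 1L
    cw <- width_map[ry, rx] * w
    ch <- height_map[ry, rx] * h
    rows[[length(rows) + 1L]] <- data.frame(
      x_topleft = cen[1] - cw / 2, y_topleft = cen[2] - ch / 2,
      width = cw, height = ch,
      centroid_x = cen[1], centroid_y = cen[2],
      score = heatmap[ry, rx])
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Encode a full training target
#'
#' Convenience wrapper combining [encode_heatmap()] and [encode_size_maps()].
#'
#' @inheritParams encode_heatmap
#' @return List with `heatmap`, `width_map`, `height_map`.
#' @export
encode_targets <- function(annotations, image_size) {
  sm <- encode_size_maps(annotations, image_size)
  list(heatmap = encode_heatmap(annotations, image_size),
       width_map = sm$width_map, height_map = sm$height_map)
}
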