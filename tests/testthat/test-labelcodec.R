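test_that("box kernels floor-divide by 1.5 and are forced odd", {
  expect_equal(box_kernel(30, 15), c(21L, 11L))
  expect_equal(box_kernel(1, 1), c(1L, 1L))
  expect_equal(box_kernel(3, 3), c(3L, 3L))   # 3 %/% 1.5 = 2, bumped to 3
  expect_true(all(box_kernel(40, 24) %% 2 == 1))
})

test_that("heatmap encoding produces smoothed unit-peak ellipses", {
  expect_equal(encode_heatmap(NULL, c(32, 32)), matrix(0, 32, 32))

  ann <- data.frame(label_id = 1L, centroid_x = 50, centroid_y = 50,
                    width = 20, height = 20)
  h <- encode_heatmap(ann, c(128, 128))
  expect_true(all(h >= 0 & h <= 1))
  peak <- which(h == max(h), arr.ind = TRUE)
  # 0-based peak location at the centroid
  expect_true(any(abs(peak[, 1] - 1 - 50) <= 0.5 & abs(peak[, 2] - 1 - 50) <= 0.5))
  expect_gt(max(h), 0.75)

  # translation equivariance for interior cells
  ann2 <- ann; ann2$centroid_x <- 57; ann2$centroid_y <- 45
  h2 <- encode_heatmap(ann2, c(128, 128))
  expect_equal(h2[(45 - 20):(45 + 20) + 1, (57 - 20):(57 + 20) + 1],
               h[(50 - 20):(50 + 20) + 1, (50 - 20):(50 + 20) + 1],
               tolerance = 1e-12)

  # two far-apart identical cells give two identical local maxima
  ann3 <- rbind(ann, transform(ann, centroid_x = 90, centroid_y = 90))
  h3 <- encode_heatmap(ann3, c(128, 128))
  expect_equal(h3[51, 51], h3[91, 91], tolerance = 1e-12)
})

test_that("size maps carry relative dimensions in half-size rectangles", {
  sm <- encode_size_maps(NULL, c(16, 16))
  expect_equal(sm$width_map, matrix(0, 16, 16))

  ann <- data.frame(label_id = 1L, centroid_x = 100, centroid_y = 100,
                    width = 64, height = 32)
  sm <- encode_size_maps(ann, c(384, 384))
  expect_equal(sm$width_map[101, 101], 64 / 384)
  expect_equal(sm$height_map[101, 101], 32 / 384)
  # rectangle spans roughly w/2 x h/2 centered on the cell
  nz <- which(sm$width_map > 0, arr.ind = TRUE)
  expect_lte(diff(range(nz[, 2])) + 1, 64 / 2 + 1)
  expect_lte(diff(range(nz[, 1])) + 1, 32 / 2 + 1)
  expect_equal(sm$width_map[101, 150], 0)   # outside the rectangle

  # nested cells: contested pixels carry the larger cell's values
  big <- data.frame(label_id = 2L, centroid_x = 100, centroid_y = 100,
                    width = 120, height = 120)
  sm2 <- encode_size_maps(rbind(ann, big), c(384, 384))
  expect_equal(sm2$width_map[101, 101], 120 / 384)
})

test_that("blob thresholding is strictly greater than 0.75", {
  expect_false(any(threshold_blobs(matrix(0, 8, 8))))
  expect_false(any(threshold_blobs(matrix(0.75, 8, 8))))
  m <- matrix(0, 8, 8); m[3:4, 5:6] <- 0.8
  tb <- threshold_blobs(m)
  expect_equal(sum(tb), 4L)
  expect_true(all(tb[3:4, 5:6]))
})

test_that("blob labeling is 8-connected and raster-ordered", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # diagonal touch: one component
  m[5, 5] <- TRUE
  lab <- label_blobs(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("blob centroids follow raw image moments", {
  expect_equal(blob_centroid(7, 3), c(7, 3))
  expect_equal(blob_centroid(c(10, 10, 11, 11), c(10, 11, 10, 11)),
               c(10.5, 10.5))
  expect_equal(blob_centroid(c(0, 1, 0), c(0, 0, 1)), c(1 / 3, 1 / 3))
  expect_error(blob_centroid(numeric(), numeric()))
})

test_that("decode recovers encoded cells to pixel accuracy", {
  ann <- data.frame(label_id = 1L, centroid_x = 64, centroid_y = 64,
                    width = 40, height = 24)
  tg <- encode_targets(ann, c(192, 192))
  det <- decode_detections(tg$heatmap, tg$width_map, tg$height_map)
  expect_equal(nrow(det), 1L)
  expect_lte(abs(det$centroid_x - 64), 1)
  expect_lte(abs(det$centroid_y - 64), 1)
  expect_lte(abs(det$width - 40), 1)
  expect_lte(abs(det$height - 24), 1)
  expect_equal(det$x_topleft, det$centroid_x - det$width / 2)
  expect_gt(det$score, 0.75)

  expect_equal(nrow(decode_detections(matrix(0, 64, 64), matrix(0, 64, 64),
                                      matrix(0, 64, 64))), 0L)

  ann2 <- rbind(ann, data.frame(label_id = 2L, centroid_x = 150,
                                centroid_y = 40, width = 30, height = 30))
  tg2 <- encode_targets(ann2, c(192, 192))
  det2 <- decode_detections(tg2$heatmap, tg2$width_map, tg2$height_map)
  expect_equal(nrow(det2), 2L)
  errs <- match_detections(det2, ann2)
  expect_lte(max(errs[, "centroid"]), 1)
  expect_lte(max(errs[, c("width", "height")]), 1)
})

test_that("tiny blobs below the minimum area are discarded", {
  h <- matrix(0, 32, 32)
  h[5, 5] <- 0.9            # single-pixel noise
  h[20:23, 20:23] <- 0.9    # real blob
  wm <- matrix(0.5, 32, 32); hm <- matrix(0.5, 32, 32)
  det <- decode_detections(h, wm, hm)
  expect_equal(nrow(det), 1L)
  expect_gt(det$centroid_x, 15)
})

test_that("decode is invariant to monotone rescaling above the threshold", {
  ann <- data.frame(label_id = 1:2,
                    centroid_x = c(40, 120), centroid_y = c(40, 120),
                    width = c(30, 24), height = c(20, 28))
  tg <- encode_targets(ann, c(160, 160))
  det1 <- decode_detections(tg$heatmap, tg$width_map, tg$height_map)
  squash <- ifelse(tg$heatmap > 0.75, 0.76 + 0.2 * (tg$heatmap - 0.75),
                   tg$heatmap * 0.9)
  det2 <- decode_detections(squash, tg$width_map, tg$height_map)
  expect_equal(det2[, c("x_topleft", "y_topleft", "width", "height")],
               det1[, c("x_topleft", "y_topleft", "width", "height")])
})

test_that("codec round-trips randomized well-separated scenes", {
  for (sd in 1:15) {
    sc <- generate_scene(scene_spec(image_size = c(192L, 192L),
                                    n_cells = c(3L, 6L),
                                    axis_range = c(5, 12),
                                    min_separation = 45, seed = sd))
    tg <- encode_targets(sc$annotations, c(192, 192))
    det <- decode_detections(tg$heatmap, tg$width_map, tg$height_map)
    expect_equal(nrow(det), nrow(sc$annotations))
    errs <- match_detections(det, sc$annotations)
    expect_lte(max(errs[, "centroid"]), 1)
    expect_lte(max(errs[, c("width", "height")]), 1)
  }
})
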