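test_that("context block gates slices exactly as specified", {
  m <- build_model(model_config(input_size = 64L), seed = 1L)
  # zero convolution weights: channels 1 and 3 become sigmoid(S_cur)
  mz <- m
  for (p in c("context_prev", "context_next")) {
    for (i in seq_along(mz$parts[[p]])) {
      mz$parts[[p]][[i]]$W[] <- 0
      mz$parts[[p]][[i]]$b[] <- 0
    }
  }
  z <- matrix(0, 16, 16)
  out <- context_block(z, z, z, mz)
  expect_equal(out[, , 1], matrix(0.5, 16, 16))
  expect_equal(out[, , 2], z)
  expect_equal(out[, , 3], matrix(0.5, 16, 16))

  s <- matrix(stats::runif(256), 16, 16)
  outs <- context_block(s, s, s, mz)
  expect_equal(outs[, , 1], 1 / (1 + exp(-s)))

  # channel 2 is always the untouched current slice
  out2 <- context_block(matrix(stats::runif(256), 16, 16), s,
                        matrix(stats::runif(256), 16, 16), m)
  expect_identical(out2[, , 2], s)

  # shared branch parameters make the block symmetric in prev/next
  ms <- build_model(model_config(input_size = 64L, shared_context = TRUE),
                    seed = 4L)
  out3 <- context_block(s, matrix(0.3, 16, 16), s, ms)
  expect_equal(out3[, , 1], out3[, , 3])
})

test_that("model outputs match the configured top's shape and range", {
  m <- build_model(model_config(input_size = 64L), seed = 2L)
  x <- matrix(stats::runif(64 * 64), 64, 64)
  fw <- model_forward(m, x)
  expect_equal(dim(fw$heatmap), c(64L, 64L))
  expect_equal(dim(fw$size), c(64L, 64L, 2L))
  expect_true(all(fw$heatmap > 0 & fw$heatmap < 1))
  expect_true(all(fw$size > 0 & fw$size < 1))

  mp <- build_model(model_config(input_size = 64L, top = "pretrain_rgb"),
                    seed = 2L)
  fwp <- model_forward(mp, x)
  expect_equal(dim(fwp$rgb), c(64L, 64L, 3L))

  expect_error(build_model(model_config(backbone = "efficientnet_v2s")),
               "not bundled")
})

test_that("model construction and forward passes are deterministic", {
  m1 <- build_model(model_config(input_size = 64L), seed = 9L)
  m2 <- build_model(model_config(input_size = 64L), seed = 9L)
  expect_identical(model_checksums(m1), model_checksums(m2))
  x <- matrix(stats::runif(64 * 64), 64, 64)
  expect_identical(model_forward(m1, x), model_forward(m2, x))
})

test_that("swapping the top preserves every other parameter", {
  m <- build_model(model_config(input_size = 64L, top = "pretrain_rgb"),
                   seed = 3L)
  before <- model_checksums(m)
  md <- swap_top(m, "detect", seed = 8L)
  after <- model_checksums(md)
  keep <- c("context_prev", "context_next", "backbone", "neck", "head_trunk")
  expect_identical(after[keep], before[keep])
  expect_equal(md$cfg$top, "detect")
  # swap back: non-top parts still untouched
  back <- model_checksums(swap_top(md, "pretrain_rgb", seed = 10L))
  expect_identical(back[keep], before[keep])
})

test_that("analytic gradients agree with finite differences", {
  m <- build_model(model_config(input_size = 16L, top = "pretrain_rgb"),
                   seed = 5L)
  set.seed(6)
  x <- matrix(stats::runif(16 * 16), 16, 16)
  tgt <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  lossfn <- function(model) mse_reconstruction(model_forward(model, x)$rgb, tgt)
  fw <- model_forward(m, x, with_cache = TRUE)
  g <- pseudocell:::model_backward(m, fw$cache,
                                   list(rgb = 2 * (fw$rgb - tgt) / length(tgt)))
  eps <- 1e-6
  for (part in c("backbone", "neck", "context_prev", "context_next")) {
    m2 <- m
    m2$parts[[part]][[1]]$W[2, 1] <- m2$parts[[part]][[1]]$W[2, 1] + eps
    num <- (lossfn(m2) - lossfn(m)) / eps
    expect_equal(g[[part]][[1]]$dW[2, 1], num, tolerance = 1e-4)
  }
  m2 <- m
  m2$parts$head_trunk[[2]]$W[3, 2] <- m2$parts$head_trunk[[2]]$W[3, 2] + eps
  expect_equal(g$head_trunk[[2]]$dW[3, 2], (lossfn(m2) - lossfn(m)) / eps,
               tolerance = 1e-4)
})

test_that("parameter counts are conserved across parts and swaps", {
  m <- build_model(model_config(input_size = 64L), seed = 1L)
  parts <- c("backbone", "neck", "heads", "context_block")
  total <- sum(vapply(parts, function(p) count_parameters(m, p), 0L))
  expect_equal(count_parameters(m, "total"), total)
  expect_lte(count_parameters(m, "total"), 200000L)

  mp <- swap_top(m, "pretrain_rgb", seed = 2L)
  for (p in c("backbone", "neck", "context_block")) {
    expect_equal(count_parameters(mp, p), count_parameters(m, p))
  }
})

test_that("checkpoints round-trip through JSON", {
  m <- build_model(model_config(input_size = 64L), seed = 11L)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_checksums(m2), model_checksums(m))
  x <- matrix(stats::runif(64 * 64), 64, 64)
  expect_equal(model_forward(m2, x), model_forward(m, x), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "format")
})

test_that("3D stacks flow through triplets into the detector", {
  st <- generate_stack(scene_spec(image_size = c(64L, 64L), n_cells = 2L,
                                  axis_range = c(5, 9), min_separation = 25,
                                  seed = 31L), depth = 5)
  trips <- slice_triplets(st$volume)
  expect_length(trips, 5L)
  m <- build_model(model_config(input_size = 64L), seed = 1L)
  tr <- trips[[3]]
  fw <- model_forward(m, tr$cur, s_prev = tr$prev, s_next = tr$nxt)
  expect_equal(dim(fw$heatmap), c(64L, 64L))
})
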