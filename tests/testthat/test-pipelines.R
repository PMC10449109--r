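test_that("run configurations carry the documented defaults", {
  cfg <- run_config(task = "pretrain", model = model_config(input_size = 64L))
  expect_equal(cfg$epochs, 75L)
  expect_equal(cfg$optimizer$lr, 1e-4)
  expect_equal(cfg$optimizer$lr_min, 1e-6)
  expect_equal(cfg$optimizer$plateau_factor, 10)
  expect_equal(cfg$batch_size, 32L)

  auto <- run_config(task = "pretrain", colormap = "gray_identity",
                     model = model_config(input_size = 64L))
  expect_equal(auto$epochs, 50L)   # plain autoencoding converges faster

  det <- run_config(task = "train", model = model_config())
  expect_equal(det$epochs, 50L)
  expect_equal(det$batch_size, 8L)

  expect_error(run_config(task = "train", lr = 1e-7, lr_min = 1e-6,
                          model = model_config(input_size = 64L)))
})

test_that("YAML run configs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    task = "train",
    model = list(input_size = 64L, freeze = "backbone"),
    lr = 1e-3, epochs = 2L, batch_size = 4L, seed = 5L,
    mask = list(scheme = "padded", seed = 2L),
    data = list(scene = list(image_size = c(64L, 64L), n_cells = 3L,
                             axis_range = c(4, 8), min_separation = 18),
                n_images = 4L)), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$task, "train")
  expect_equal(cfg$model$freeze, "backbone")
  expect_equal(cfg$optimizer$lr, 1e-3)
  expect_equal(cfg$mask$scheme, "padded")
  expect_equal(cfg$data$scene$n_cells, 3L)
})

test_that("pretraining runs are reproducible and honour the loss contract", {
  cfg <- smoke_pretrain_config(seed = 41L, n_images = 6L, epochs = 2L)
  r1 <- pretrain(cfg)
  r2 <- pretrain(cfg)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 2L)
  expect_true(all(r1$history$ssim <= 1))
  expect_identical(r1$config$seed, cfg$seed)
})

test_that("plain autoencoding is the same path with identity colormap", {
  cfg <- smoke_pretrain_config(seed = 42L, n_images = 4L, epochs = 1L,
                               mask = NULL, colormap = "gray_identity")
  r <- pretrain(cfg)
  expect_equal(nrow(r$history), 1L)
  expect_true(is.finite(r$history$loss))
})

test_that("detection training logs a conserved weighted loss", {
  cfg <- smoke_train_config(seed = 43L, n_images = 6L, epochs = 2L)
  r <- train_detect(cfg)
  expect_identical(r$history$l_total,
                   r$history$l_heatmap + 0.5 * r$history$l_height +
                     0.5 * r$history$l_width)
  expect_equal(nrow(r$history), 2L)
  expect_true(all(r$history$miou >= 0 & r$history$miou <= 1))
})

test_that("freeze modes gate exactly the intended parts during training", {
  run_one <- function(freeze) {
    cfg <- smoke_train_config(seed = 44L, n_images = 4L, freeze = freeze,
                              epochs = 1L)
    cfg$batch_size <- 4L  # exactly one optimizer step
    m0 <- build_model({
      mc <- cfg$model; mc$top <- "detect"; mc
    }, seed = cfg$seed)
    before <- model_checksums(m0)
    after <- model_checksums(train_detect(cfg)$model)
    list(before = before, after = after)
  }

  he <- run_one("backbone_and_neck")
  expect_identical(he$after["backbone"], he$before["backbone"])
  expect_identical(he$after["neck"], he$before["neck"])
  expect_false(he$after["top"] == he$before["top"])

  be <- run_one("backbone")
  expect_identical(be$after["backbone"], be$before["backbone"])
  expect_false(be$after["neck"] == be$before["neck"])

  ft <- run_one("none")
  expect_false(ft$after["backbone"] == ft$before["backbone"])
  expect_false(ft$after["neck"] == ft$before["neck"])
})

test_that("a pretraining checkpoint changes initial weights, not shape", {
  pre <- pretrain(smoke_pretrain_config(seed = 45L, n_images = 4L,
                                        epochs = 1L))
  cfg <- smoke_train_config(seed = 46L, n_images = 4L, epochs = 1L)
  warm <- train_detect(cfg, init_model = pre$model)
  cold <- train_detect(cfg)
  expect_equal(count_parameters(warm$model, "total"),
               count_parameters(cold$model, "total"))
  expect_false(model_checksums(warm$model)["backbone"] ==
                 model_checksums(cold$model)["backbone"])
})

test_that("evaluation reports mIoU and writes COCO files", {
  cfg <- smoke_train_config(seed = 47L, n_images = 4L, epochs = 1L)
  r <- train_detect(cfg)
  ds <- pseudocell:::load_dataset(cfg)
  dir <- withr::local_tempdir()
  rep <- evaluate_detector(r$model, ds, coco_dir = dir)
  expect_length(rep$miou_per_image, 4L)
  expect_true(rep$miou >= 0 && rep$miou <= 1)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "results.json")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(gt$images, 4L)

  expect_error(evaluate_detector(r$model, list()), "empty")
  expect_error(evaluate_detector(r$model,
               list(list(image = matrix(0, 64, 64), annotations = NULL))),
               "ground-truth")
})

test_that("checkpoints written by training runs reload and evaluate", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- smoke_train_config(seed = 48L, n_images = 4L, epochs = 1L)
  r <- train_detect(cfg, checkpoint = path)
  m <- load_checkpoint(path)
  expect_identical(model_checksums(m), model_checksums(r$model))
})
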