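test_that("depth maps to residual blocks as stem + 2B convs + dense", {
  cfg14 <- candidate_config(8, 3, 4, 14, "ReLU", "Adam")
  a14 <- build_resnet(cfg14, c(64, 64, 1), 4)
  expect_identical(a14$n_blocks, 6L)
  expect_identical(a14$weighted_layer_count, 14L)
  cfg20 <- candidate_config(8, 3, 4, 20, "ReLU", "Adam")
  a20 <- build_resnet(cfg20, c(64, 64, 1), 4)
  expect_identical(a20$n_blocks, 9L)
  expect_identical(a20$weighted_layer_count, 20L)
})

test_that("weighted layer count equals n_layers for all reference configurations", {
  for (cfg in realize(reference_design(), default_space())) {
    arch <- suppressWarnings(build_resnet(cfg, c(64, 64, 1), 4))
    expect_identical(arch$weighted_layer_count, cfg$n_layers)
  }
})

test_that("skip connections join identically shaped tensors", {
  for (cfg in realize(reference_design(), default_space())) {
    arch <- suppressWarnings(build_resnet(cfg, c(64, 64, 1), 4))
    blocks <- Filter(function(l) l$type == "residual_block", arch$layers)
    expect_length(blocks, arch$n_blocks)
    for (b in blocks) expect_identical(b$skip_from, b$skip_to)
  }
})

test_that("the architecture summary JSON lists layers with parameter counts", {
  arch <- build_resnet(candidate_config(8, 5, 4, 14, "Tanh", "SGD"),
                       c(64, 64, 1), 4)
  f <- tempfile(fileext = ".json")
  write_architecture_json(arch, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$weighted_layer_count, 14)
  expect_length(js$layers, 10L)     # stem, stem pool, 6 blocks, pool, dense
  expect_equal(js$layers[[1]]$n_params, (5 * 5 + 1) * 8)
  expect_equal(js$layers[[3]]$n_params, 2 * (8 * 25 + 1) * 8)
})

test_that("invalid depths and oversized pooling windows are handled", {
  cfg_odd <- candidate_config(8, 3, 4, 15, "ReLU", "Adam")
  expect_error(build_resnet(cfg_odd, c(64, 64, 1), 4), "even")
  cfg_pool <- candidate_config(8, 3, 32, 14, "ReLU", "Adam")
  expect_warning(arch <- build_resnet(cfg_pool, c(64, 64, 1), 4),
                 "clipped")
  expect_identical(arch$dims$win, 16L)           # 64 -> 32 -> 16 feature map
  pool_layer <- Filter(function(l) l$name == "pool", arch$layers)[[1]]
  expect_identical(pool_layer$output_shape[1:2], c(1L, 1L))
})

test_that("training a single-class task reaches accuracy 1 with flat loss", {
  imgs <- generate_oct_like(c(8, 0, 0, 0), c(32, 32), seed = 2)
  solo <- labeled_image_set(imgs$images, imgs$labels, class_labels = "CNV")
  cfg <- candidate_config(8, 3, 4, 14, "ReLU", "Adam")
  arch <- build_resnet(cfg, c(32, 32, 1), 1)
  proto <- training_protocol(epochs = 2, batch_size = 4,
                             input_resize = c(32, 32), seed = 5)
  m <- train_model(arch, solo, NULL, proto)
  expect_identical(m$train_accuracy, 1)
  expect_true(all(diff(m$loss_history) <= 1e-8))
})

test_that("training is bit-reproducible for a fixed seed", {
  set <- generate_oct_like(6, c(32, 32), seed = 8)
  sp <- stratified_split(set, 0.8, seed = 1)
  cfg <- candidate_config(8, 3, 4, 14, "Tanh", "SGD")
  arch <- build_resnet(cfg, c(32, 32, 1), 4)
  proto <- training_protocol(epochs = 1, batch_size = 8,
                             input_resize = c(32, 32), seed = 77)
  m1 <- train_model(arch, sp$train, sp$validation, proto)
  m2 <- train_model(arch, sp$train, sp$validation, proto)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$train_accuracy, m2$train_accuracy)
  expect_identical(m1$validation_accuracy, m2$validation_accuracy)
})

test_that("a separable two-class task is fit to high training accuracy", {
  set4 <- generate_oct_like(200, c(64, 64), 0.1, 0.8, seed = 5)
  keep <- set4$labels %in% c("CNV", "NORMAL")
  set2 <- labeled_image_set(set4$images[keep], set4$labels[keep],
                            c("CNV", "NORMAL"))
  expect_gte(nearest_centroid_accuracy(set2), 0.95)  # separability oracle
  sp <- stratified_split(set2, 0.8, seed = 2)
  cfg <- candidate_config(8, 3, 4, 14, "ReLU", "Adam")
  arch <- build_resnet(cfg, c(64, 64, 1), 2)
  m <- train_model(arch, sp$train, sp$validation,
                   training_protocol(epochs = 10, seed = 9))
  expect_gte(m$train_accuracy, 0.95)
  # reported training accuracy is consistent with predict()
  expect_identical(mean(predict(m, sp$train) == sp$train$labels),
                   m$train_accuracy)
})

test_that("predict returns one label per image and handles empty input", {
  set <- generate_oct_like(3, c(32, 32), seed = 4)
  sp <- stratified_split(set, 0.7, seed = 3)
  cfg <- candidate_config(8, 3, 4, 14, "SELU", "SGD")
  arch <- build_resnet(cfg, c(32, 32, 1), 4)
  m <- train_model(arch, sp$train, sp$validation,
                   training_protocol(epochs = 1, batch_size = 4,
                                     input_resize = c(32, 32), seed = 1))
  expect_identical(predict(m, list()), character(0))
  one <- predict(m, set$images[1])
  expect_length(one, 1L)
  expect_true(one %in% set$class_labels)
})

test_that("a class missing from the training split raises an error", {
  set <- generate_oct_like(4, c(32, 32), seed = 6)
  keep <- set$labels != "DME"
  broken <- labeled_image_set(set$images[keep], set$labels[keep],
                              class_labels = set$class_labels)
  cfg <- candidate_config(8, 3, 4, 14, "ReLU", "Adam")
  arch <- build_resnet(cfg, c(32, 32, 1), 4)
  proto <- training_protocol(epochs = 1, input_resize = c(32, 32), seed = 1)
  expect_error(train_model(arch, broken, NULL, proto), "DME")
})
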