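ref <- reference_experiment()
ref_train_acc <- as.matrix(ref$train_accuracy[, c("acc_1", "acc_2", "acc_3")])

test_that("stratified splits are class-balanced, disjoint, and guarded", {
  set <- tiny_image_set(10, seed = 4)
  sp <- stratified_split(set, 0.8, seed = 9)
  expect_identical(as.integer(table(factor(sp$train$labels,
                                           set$class_labels))), rep(8L, 4))
  expect_identical(as.integer(table(factor(sp$validation$labels,
                                           set$class_labels))), rep(2L, 4))
  expect_length(intersect(uedtune:::image_fingerprints(sp$train),
                          uedtune:::image_fingerprints(sp$validation)), 0L)
  sp2 <- stratified_split(set, 0.8, seed = 9)
  expect_identical(sp, sp2)
  lone <- labeled_image_set(set$images[1], set$labels[1], set$class_labels)
  expect_error(stratified_split(lone, 0.8, 1), "degenerate")
})

test_that("run_combination draws p distinct replicate seeds, deterministically", {
  set <- tiny_image_set(6, seed = 2)
  trainer <- perfect_stub_trainer()
  res <- run_combination(candidate_config(8, 3, 4, 14, "ReLU", "Adam"),
                         set, p = 3, base_seed = 100, trainer = trainer)
  expect_length(res, 3L)
  seeds <- vapply(res, `[[`, integer(1), "seed")
  expect_identical(seeds, c(101L, 102L, 103L))
  res2 <- run_combination(candidate_config(8, 3, 4, 14, "ReLU", "Adam"),
                          set, p = 3, base_seed = 100, trainer = trainer)
  expect_identical(lapply(res, `[`, c("train_accuracy", "seed")),
                   lapply(res2, `[`, c("train_accuracy", "seed")))
  one <- run_combination(candidate_config(8, 3, 4, 14, "ReLU", "Adam"),
                         set, p = 1, base_seed = 1, trainer = trainer)
  expect_length(one, 1L)
  expect_error(replicate_stats(vapply(one, `[[`, numeric(1),
                                      "train_accuracy")), "at least 2")
})

test_that("the scripted reference accuracies reproduce the published table", {
  set <- tiny_image_set(4, seed = 3)
  trainer <- accuracy_stub_trainer(ref_train_acc, ref_train_acc)
  tab <- run_uniform_experiment(reference_design(), default_space(), set,
                                p = 3, base_seed = 1, trainer = trainer,
                                verbose = FALSE)
  expect_identical(nrow(tab), 12L)
  for (i in seq_len(12)) {
    expect_equal(tab$train_mean[i], ref$train_accuracy$mean[i],
                 tolerance = 1e-4)
    expect_equal(tab$train_sd[i], ref$train_accuracy$sd[i],
                 tolerance = 1e-3)
    expect_lt(abs(tab$train_snr[i] - ref$train_accuracy$snr[i]), 0.01)
  }
  expect_equal(tab$snr_sum, tab$train_snr + tab$val_snr)
})

test_that("identical accuracies across combinations give equal summed SNRs", {
  set <- tiny_image_set(4, seed = 3)
  flat <- matrix(0.93, 12, 3)
  tab <- run_uniform_experiment(reference_design(), default_space(), set,
                                p = 3, base_seed = 1,
                                trainer = accuracy_stub_trainer(flat, flat),
                                verbose = FALSE)
  expect_equal(diff(range(tab$snr_sum)), 0)
})

test_that("experiment logging carries combination and replicate indices", {
  set <- tiny_image_set(4, seed = 3)
  trainer <- accuracy_stub_trainer(ref_train_acc, ref_train_acc)
  expect_message(
    run_uniform_experiment(reference_design(), default_space(), set, p = 3,
                           base_seed = 1, trainer = trainer, verbose = TRUE),
    "combination 2 replicate 1")
})

test_that("selection maximizes summed SNR with deterministic tie-breaks", {
  sel <- select_best(data.frame(combination = 1:12,
                                snr_sum = ref$snr$train_snr +
                                  ref$snr$val_snr))
  expect_identical(sel$best_index, 4L)
  single <- select_best(data.frame(combination = 7L, snr_sum = 10))
  expect_identical(single$best_index, 7L)
  tied <- select_best(data.frame(combination = 1:3,
                                 snr_sum = c(5, 9, 9)))
  expect_identical(tied$best_index, 2L)
  dom <- select_best(data.frame(combination = 1:3,
                                snr_sum = c(50, Inf, 60)))
  expect_identical(dom$best_index, 2L)
  expect_error(select_best(data.frame()), "empty")
})

test_that("test evaluation retrains on fresh groupings and guards overlap", {
  set <- tiny_image_set(6, seed = 12)
  test_set <- tiny_image_set(3, seed = 13)
  cfg <- candidate_config(8, 3, 4, 14, "ReLU", "Adam")
  rep3 <- evaluate_on_test(cfg, set, test_set, p = 3, base_seed = 5,
                           trainer = perfect_stub_trainer())
  expect_identical(rep3$accuracy, rep(1, 3))
  expect_identical(rep3$fnr, rep(0, 3))
  expect_identical(rep3$mean_accuracy, 1)
  expect_identical(rep3$sd_accuracy, 0)
  expect_length(rep3$confusions, 3L)
  rep1 <- evaluate_on_test(cfg, set, test_set, p = 1, base_seed = 5,
                           trainer = perfect_stub_trainer())
  expect_identical(rep1$accuracy, 1)
  expect_identical(rep1$fnr, 0)
  expect_error(evaluate_on_test(cfg, set, set, p = 1, base_seed = 5,
                                trainer = perfect_stub_trainer()),
               "overlap")
})

test_that("published test replicates average to the published summary", {
  st <- replicate_stats(ref$test$accuracy)
  expect_lt(abs(st$mean - ref$test_mean_accuracy), 1e-4)
  expect_lt(abs(st$std - ref$test_sd_accuracy), 1e-4)
  expect_lt(abs(mean(ref$test$fnr) - ref$test_mean_fnr), 1e-4)
})

test_that("a small real-trainer experiment is end-to-end deterministic", {
  set <- generate_oct_like(10, c(32, 32), seed = 21)
  design <- uedtune:::mixed_level_design(
    matrix(c(1L, 1L, 1L, 1L, 4L, 2L,
             2L, 2L, 2L, 2L, 1L, 1L), nrow = 2, byrow = TRUE),
    c(2L, 2L, 4L, 2L, 4L, 2L))
  proto <- training_protocol(epochs = 1, batch_size = 16,
                             input_resize = c(32, 32), seed = 1)
  run_once <- function(dir) {
    tab <- run_uniform_experiment(design, default_space(), set, p = 2,
                                  base_seed = 3, protocol = proto,
                                  verbose = FALSE)
    render_reports(tab, dir = dir)
    tab
  }
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- run_once(d1); t2 <- run_once(d2)
  expect_identical(t1, t2)
  for (f in c("train_accuracy.csv", "snr_summary.csv", "results.json"))
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))))
  sel <- select_best(t1)
  expect_true(all(sel$summed_snr >= t1$snr_sum))
})
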