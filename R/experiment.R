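#' Stratified random data grouping
#'
#' Splits a modeling pool into train/validation groupings, stratified by
#' class: per class, `round(train_fraction * n)` images (clamped so both
#' sides keep at least one image) go to the training split. Redrawn with a
#' fresh seed per replicate, this is the "random data grouping" of the
#' replicated uniform experiment.
#'
#' @param set a [labeled_image_set()] with at least 2 images per class.
#' @param train_fraction training fraction in (0, 1).
#' @param seed integer split seed.
#' @return `list(train =, validation =)` of disjoint image sets.
#' @export
stratified_split <- function(set, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(set, "labeled_image_set"),
            train_fraction > 0, train_fraction < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tr_idx <- integer(0)
  for (cl in set$class_labels) {
    idx <- which(set$labels == cl)
    n <- length(idx)
    if (n < 2L)
      stop(sprintf(
        "degenerate split: class '%s' has %d image(s); need at least 2",
        cl, n), call. = FALSE)
    n_tr <- min(max(round(train_fraction * n), 1L), n - 1L)
    tr_idx <- c(tr_idx, sample(idx, n_tr))
  }
  tr_idx <- sort(tr_idx)
  list(train = subset_image_set(set, tr_idx),
       validation = subset_image_set(set, setdiff(seq_along(set$labels),
                                                  tr_idx)))
}

#' Run the replicates of one hyperparameter combination
#'
#' Trains `p` models for one configuration, each on a fresh stratified
#' train/validation grouping drawn with seed `base_seed + j` (replicate
#' `j`); the same seed is used for the training run itself, so the whole
#' replicate is reproducible.
#'
#' @param config a [candidate_config()].
#' @param dataset the modeling pool, a [labeled_image_set()].
#' @param p number of replicates (>= 1; replicate statistics need >= 2).
#' @param base_seed integer base seed.
#' @param protocol a [training_protocol()].
#' @param trainer a trainer function (default [resnet_trainer()]).
#' @param combination combination index forwarded to the trainer.
#' @param verbose emit one log line per replicate (carries the combination
#'   index and replicate number).
#' @return A list of `p` results, each
#'   `list(train_accuracy, validation_accuracy, seed, model)`.
#' @export
run_combination <- function(config, dataset, p = 3L, base_seed = 1L,
                            protocol = training_protocol(),
                            trainer = resnet_trainer(), combination = 1L,
                            verbose = FALSE) {
  stopifnot(p >= 1L)
  lapply(seq_len(p), function(j) {
    seed_j <- as.integer(base_seed + j)
    grouping <- stratified_split(dataset, protocol$train_fraction, seed_j)
    proto_j <- protocol; proto_j$seed <- seed_j
    res <- trainer(config, grouping$train, grouping$validation, proto_j,
                   info = list(combination = combination, replicate = j))
    if (verbose)
      message(sprintf(
        "combination %d replicate %d (seed %d): train=%.4f val=%.4f",
        combination, j, seed_j, res$train_accuracy,
        res$validation_accuracy))
    list(train_accuracy = res$train_accuracy,
         validation_accuracy = res$validation_accuracy,
         seed = seed_j, model = res$model)
  })
}

#' Run the full uniform experiment
#'
#' Realizes every design row into a configuration, runs `p` replicates per
#' combination with fresh random data groupings, and tabulates replicate
#' train/validation accuracies, their mean, standard deviation and
#' nominal-the-best SNR, and the summed train+validation SNR used for
#' selection. Combination `i` uses base seed `base_seed + (i - 1) * p`, so
#' all `n x p` replicate seeds are distinct and reproducible.
#'
#' @param design a `mixed_level_design` (e.g. [reference_design()]).
#' @param space factor space matching the design (default
#'   [default_space()]).
#' @inheritParams run_combination
#' @return An `experiment_table`: a data frame with one row per combination
#'   and columns `combination`, `train_acc_<j>`, `train_mean`, `train_sd`,
#'   `train_snr`, `val_acc_<j>`, `val_mean`, `val_sd`, `val_snr`,
#'   `snr_sum`.
#' @export
run_uniform_experiment <- function(design, space = default_space(), dataset,
                                   p = 3L, base_seed = 1L,
                                   protocol = training_protocol(),
                                   trainer = resnet_trainer(),
                                   verbose = TRUE) {
  stopifnot(p >= 2L)
  configs <- realize(design, space)
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    res <- tryCatch(
      run_combination(configs[[i]], dataset, p,
                      base_seed = base_seed + (i - 1L) * p,
                      protocol = protocol, trainer = trainer,
                      combination = i, verbose = verbose),
      error = function(e) stop(sprintf("combination %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    tr <- vapply(res, `[[`, numeric(1L), "train_accuracy")
    va <- vapply(res, `[[`, numeric(1L), "validation_accuracy")
    st_tr <- replicate_stats(tr); st_va <- replicate_stats(va)
    row <- c(list(combination = i),
             stats::setNames(as.list(tr), paste0("train_acc_", seq_len(p))),
             list(train_mean = st_tr$mean, train_sd = st_tr$std,
                  train_snr = snr(st_tr$mean, st_tr$std)),
             stats::setNames(as.list(va), paste0("val_acc_", seq_len(p))),
             list(val_mean = st_va$mean, val_sd = st_va$std,
                  val_snr = snr(st_va$mean, st_va$std)))
    row$snr_sum <- row$train_snr + row$val_snr
    rows[[i]] <- as.data.frame(row)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "p") <- p
  attr(tab, "base_seed") <- base_seed
  attr(tab, "configs") <- configs
  class(tab) <- c("experiment_table", "data.frame")
  tab
}

#' Select the most robust hyperparameter combination
#'
#' The winner maximizes the summed train+validation SNR; ties break towards
#' the smallest combination index, and `+Inf` (a perfectly on-target,
#' zero-dispersion combination) dominates.
#'
#' @param table an `experiment_table` (or any data frame with columns
#'   `combination` and `snr_sum`).
#' @return `list(best_index =, best_config = (when available), summed_snr =)`.
#' @export
select_best <- function(table) {
  if (is.null(table) || nrow(table) == 0L)
    stop("empty experiment table", call. = FALSE)
  if (any(is.na(table$snr_sum)))
    stop("experiment table contains missing SNR sums", call. = FALSE)
  best <- which.max(table$snr_sum)     # first maximum = smallest index
  configs <- attr(table, "configs")
  list(best_index = table$combination[best],
       best_config = if (!is.null(configs))
         configs[[table$combination[best]]],
       summed_snr = table$snr_sum[best])
}

#' Final test evaluation of a configuration
#'
#' Retrains `p` models on fresh random groupings of the modeling pool and
#' evaluates each on the fixed, held-out test set, reporting per-replicate
#' test accuracy and macro false negative rate plus their means and the
#' accuracy standard deviation. Errors if any test image also occurs in the
#' modeling pool.
#'
#' @param config the selected [candidate_config()].
#' @param dataset the modeling pool.
#' @param test_set the held-out test [labeled_image_set()]; must be disjoint
#'   from `dataset`.
#' @inheritParams run_combination
#' @return A `test_report`: list with `accuracy`, `fnr` (length-`p`
#'   vectors), `mean_accuracy`, `mean_fnr`, `sd_accuracy`, `seeds`, and
#'   `confusions` (one [confusion_matrix()] per replicate).
#' @export
evaluate_on_test <- function(config, dataset, test_set, p = 3L,
                             base_seed = 1L, protocol = training_protocol(),
                             trainer = resnet_trainer()) {
  stopifnot(inherits(test_set, "labeled_image_set"))
  if (length(intersect(image_fingerprints(dataset),
                       image_fingerprints(test_set))))
    stop("modeling pool and test set overlap", call. = FALSE)
  acc <- numeric(p); fnr <- numeric(p); seeds <- integer(p)
  confusions <- vector("list", p)
  for (j in seq_len(p)) {
    seed_j <- as.integer(base_seed + j)
    grouping <- stratified_split(dataset, protocol$train_fraction, seed_j)
    proto_j <- protocol; proto_j$seed <- seed_j
    res <- trainer(config, grouping$train, grouping$validation, proto_j,
                   info = list(combination = 1L, replicate = j))
    if (is.function(res$model)) {          # stub seam: model as predictor
      pred <- res$model(test_set)
    } else if (!is.null(res$model)) {
      pred <- predict(res$model, test_set)
    } else stop("trainer returned no model to evaluate", call. = FALSE)
    cm <- confusion_matrix(test_set$labels, pred,
                           class_labels = test_set$class_labels)
    acc[j] <- accuracy(cm); fnr[j] <- false_negative_rate(cm)
    seeds[j] <- seed_j; confusions[[j]] <- cm
  }
  structure(list(accuracy = acc, fnr = fnr,
                 mean_accuracy = mean(acc), mean_fnr = mean(fnr),
                 sd_accuracy = if (p >= 2L) stats::sd(acc) else NA_real_,
                 seeds = seeds, confusions = confusions),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat("test_report:\n")
  for (j in seq_along(x$accuracy))
    cat(sprintf("  replicate %d: accuracy %.4f, FNR %.4f\n", j,
                x$accuracy[j], x$fnr[j]))
  cat(sprintf("  mean accuracy %.4f (sd %s), mean FNR %.4f\n",
              x$mean_accuracy,
              ifelse(is.na(x$sd_accuracy), "NA",
                     sprintf("%.4f", x$sd_accuracy)), x$mean_fnr))
  invisible(x)
}
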