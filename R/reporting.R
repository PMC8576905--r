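#' Render experiment reports
#'
#' Writes the three report tables of a full run plus a full-precision JSON
#' bundle into `dir`:
#' \describe{
#'   \item{train_accuracy.csv}{per-combination replicate training
#'     accuracies, mean, standard deviation and SNR;}
#'   \item{snr_summary.csv}{training SNR, validation SNR and their sum per
#'     combination;}
#'   \item{test_results.csv}{per-replicate test accuracy and false negative
#'     rate with a trailing mean row (omitted when no test report is
#'     given);}
#'   \item{results.json}{everything above at full precision, plus the
#'     selection result.}
#' }
#' CSV cells are rounded half-up — accuracies and means to 4 decimals,
#' standard deviations to 6, SNRs to 2 — and written comma-separated,
#' UTF-8, Unix newlines, so re-rendering identical inputs yields
#' byte-identical files.
#'
#' @param table a complete `experiment_table` from
#'   [run_uniform_experiment()].
#' @param test_report optional `test_report` from [evaluate_on_test()].
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(table, test_report = NULL, dir = ".") {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  expected <- seq_len(max(table$combination))
  missing <- setdiff(expected, table$combination)
  if (length(missing))
    stop(sprintf("partial experiment table: missing combination(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- sum(grepl("^train_acc_", names(table)))

  fmt <- function(x, digits)
    formatC(round_half_up(x, digits), format = "f", digits = digits)
  files <- character(0)

  t5 <- data.frame(combination = table$combination)
  for (j in seq_len(p))
    t5[[paste0("acc_", j)]] <- fmt(table[[paste0("train_acc_", j)]], 4L)
  t5$mean <- fmt(table$train_mean, 4L)
  t5$sd <- fmt(table$train_sd, 6L)
  t5$snr <- fmt(table$train_snr, 2L)
  f <- file.path(dir, "train_accuracy.csv")
  write_csv_unix(t5, f); files <- c(files, f)

  t6 <- data.frame(combination = table$combination,
                   train_snr = fmt(table$train_snr, 2L),
                   val_snr = fmt(table$val_snr, 2L),
                   snr_sum = fmt(table$snr_sum, 2L))
  f <- file.path(dir, "snr_summary.csv")
  write_csv_unix(t6, f); files <- c(files, f)

  if (!is.null(test_report)) {
    t7 <- data.frame(
      experiment = c(seq_along(test_report$accuracy), "mean"),
      accuracy = fmt(c(test_report$accuracy, test_report$mean_accuracy), 4L),
      fnr = fmt(c(test_report$fnr, test_report$mean_fnr), 4L))
    f <- file.path(dir, "test_results.csv")
    write_csv_unix(t7, f); files <- c(files, f)
  }

  sel <- select_best(table)
  bundle <- list(
    experiment_table = as.data.frame(lapply(table, identity)),
    selection = list(best_index = sel$best_index,
                     summed_snr = sel$summed_snr),
    test_report = if (!is.null(test_report))
      test_report[c("accuracy", "fnr", "mean_accuracy", "mean_fnr",
                    "sd_accuracy", "seeds")])
  f <- file.path(dir, "results.json")
  jsonlite::write_json(bundle, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, f)
  invisible(files)
}

# Deterministic CSV: comma-separated, header, no quoting, Unix newlines.
write_csv_unix <- function(df, path) {
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(as.list(df)), sep = ",")))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Build a run manifest
#'
#' A manifest records everything needed to re-run a command: a snapshot of
#' the configuration and protocol, every seed, a design checksum, a dataset
#' fingerprint (image count plus content checksum), the package version and
#' a timestamp.
#'
#' @param command the CLI/command name.
#' @param seeds named list or vector of seeds used.
#' @param config optional configuration snapshot (any JSON-serializable
#'   list).
#' @param design optional design whose checksum to record.
#' @param dataset optional [labeled_image_set()] to fingerprint.
#' @param extra optional named list merged into the manifest.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(command, seeds = NULL, config = NULL,
                         design = NULL, dataset = NULL, extra = NULL) {
  m <- list(
    tool = "uedtune",
    version = as.character(utils::packageVersion("uedtune")),
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = config)
  if (!is.null(design))
    m$design_md5 <- digest_md5(paste(
      c(design$levels_per_factor, t(design$matrix)), collapse = ","))
  if (!is.null(dataset))
    m$dataset_fingerprint <- list(
      n_images = length(dataset),
      checksum = digest_md5(paste(image_fingerprints(dataset),
                                  collapse = ";")))
  c(m, extra)
}

#' @rdname run_manifest
#' @param manifest a manifest list.
#' @param dir directory in which to write `manifest.json`.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(f)
}

# md5 of a string via tools::md5sum (file-based, but base-only).
digest_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}
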