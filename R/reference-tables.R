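#' Published tables of the reference tuning experiment
#'
#' The package ships, as plain-text fixtures, the printed result tables of
#' the reference OCT hyperparameter-tuning experiment it reproduces: the
#' per-combination replicate training accuracies with their mean, standard
#' deviation and SNR; the train/validation/summed SNR table used for
#' selection; and the three-replicate test results of the winning
#' combination. These are the inputs for the package's arithmetic
#' reproduction checks.
#'
#' @return A list with elements
#'   \describe{
#'     \item{train_accuracy}{data frame: `combination`, `acc_1..acc_3`,
#'       `mean`, `sd`, `snr` (12 rows);}
#'     \item{snr}{data frame: `combination`, `train_snr`, `val_snr`,
#'       `snr_sum` (12 rows);}
#'     \item{test}{data frame: `experiment`, `accuracy`, `fnr` (3 replicate
#'       rows);}
#'     \item{test_mean_accuracy, test_mean_fnr, test_sd_accuracy}{the
#'       printed test summary values (0.9848, 0.0150, 0.0051).}
#'   }
#' @export
reference_experiment <- function() {
  path <- function(f) system.file("extdata", f, package = "uedtune",
                                  mustWork = TRUE)
  tr <- utils::read.csv(path("reference_train_accuracy.csv"))
  sn <- utils::read.csv(path("reference_snr.csv"))
  te <- utils::read.csv(path("reference_test.csv"),
                        colClasses = c("character", "numeric", "numeric"))
  list(train_accuracy = tr,
       snr = sn,
       test = te[te$experiment %in% c("1", "2", "3"), ],
       test_mean_accuracy = te$accuracy[te$experiment == "mean"],
       test_mean_fnr = te$fnr[te$experiment == "mean"],
       test_sd_accuracy = te$accuracy[te$experiment == "sd"])
}
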