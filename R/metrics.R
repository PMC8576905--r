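#' Confusion matrix
#'
#' Counts `counts[i, j]` = number of items whose actual class is
#' `class_labels[i]` and predicted class is `class_labels[j]` (rows actual,
#' columns predicted).
#'
#' @param actual,predicted equal-length label vectors drawn from
#'   `class_labels`.
#' @param class_labels ordered class alphabet; defaults to the sorted union
#'   of the observed labels.
#' @return A `confusion_matrix`: a q x q integer matrix with `dimnames`
#'   `list(actual = ..., predicted = ...)`.
#' @export
confusion_matrix <- function(actual, predicted,
                             class_labels = sort(unique(c(as.character(actual),
                                                          as.character(predicted))))) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("'actual' and 'predicted' must have equal length", call. = FALSE)
  unknown <- setdiff(unique(c(actual, predicted)), class_labels)
  if (length(unknown))
    stop(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  fa <- factor(actual, levels = class_labels)
  fp <- factor(predicted, levels = class_labels)
  m <- table(fa, fp)
  cm <- matrix(as.integer(m), nrow = length(class_labels),
               dimnames = list(actual = class_labels,
                               predicted = class_labels))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy from a confusion matrix
#'
#' The trace over the grand total, \eqn{\sum_i T_{ii} / \sum_{ij} T_{ij}}.
#'
#' @param cm a [confusion_matrix()] (any square count matrix is accepted).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(unclass(cm))) / sum(cm)
}

#' Macro-averaged false negative rate
#'
#' The mean over classes of the per-class miss rate
#' `(row sum - diagonal) / row sum`, i.e. one minus macro-averaged recall.
#' With balanced actual class counts this equals `1 - accuracy(cm)`.
#'
#' @param cm a square count matrix, rows actual.
#' @return Macro FNR in `[0, 1]`.
#' @export
false_negative_rate <- function(cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop(sprintf("class(es) with zero actual count: %s",
                 paste(rownames(cm)[rs == 0], collapse = ", ")),
         call. = FALSE)
  mean((rs - diag(cm)) / rs)
}

#' Replicate mean and standard deviation
#'
#' Arithmetic mean and sample standard deviation (divisor `p - 1`) of the
#' `p` replicate accuracies of one hyperparameter combination.
#'
#' @param accs numeric vector of replicate accuracies in `[0, 1]`, `p >= 2`.
#' @return `list(mean =, std =)`.
#' @export
replicate_stats <- function(accs) {
  accs <- as.numeric(accs)
  if (length(accs) < 2L)
    stop("at least 2 replicates are needed for a standard deviation",
         call. = FALSE)
  if (any(is.na(accs)) || any(accs < 0 | accs > 1))
    stop("replicate accuracies must lie in [0, 1]", call. = FALSE)
  list(mean = mean(accs), std = stats::sd(accs))
}

#' Nominal-the-best signal-to-noise ratio
#'
#' The Taguchi robustness score
#' \deqn{SNR = -10 \log_{10}\bigl[(\bar t - m)^2 + \sigma^2\bigr],}
#' which jointly rewards a replicate mean close to the target `m` (default
#' 1, i.e. perfect accuracy) and a small replicate dispersion; higher is
#' better. When the bracket is exactly zero the score is `+Inf`.
#'
#' @param mean replicate mean \eqn{\bar t}.
#' @param std replicate standard deviation \eqn{\sigma \ge 0}.
#' @param m target value (default 1).
#' @return The SNR in decibels, possibly `Inf`.
#' @examples
#' snr(0.9, 0)        # 20
#' snr(0.9754, 0.006728)
#' @export
snr <- function(mean, std, m = 1) {
  if (any(std < 0)) stop("'std' must be non-negative", call. = FALSE)
  arg <- (mean - m)^2 + std^2
  ifelse(arg == 0, Inf, -10 * log10(arg))
}

# Deterministic half-up rounding (R's round() is round-half-even); used for
# all report output: 4 decimals for accuracies, 6 for standard deviations,
# 2 for SNRs.
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
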