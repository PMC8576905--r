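#' Factor specification
#'
#' One tunable factor of the hyperparameter space: an ordered, non-empty list
#' of distinct admissible levels.
#'
#' @param name factor label (e.g. `"X1"`).
#' @param levels ordered vector of admissible values.
#' @param kind `"numeric"` or `"categorical"`.
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, levels,
                        kind = if (is.numeric(levels)) "numeric"
                               else "categorical") {
  if (length(levels) == 0L || anyDuplicated(levels))
    stop("factor levels must be non-empty and distinct", call. = FALSE)
  structure(list(name = name, kind = match.arg(kind,
                 c("numeric", "categorical")), levels = levels),
            class = "factor_spec")
}

#' The six-factor residual-network hyperparameter space
#'
#' The tuning space of the reference experiment: number of kernels X1 (8,
#' 16), kernel size X2 (3, 5), pooling size X3 (4, 8, 16, 32), weighted layer
#' count X4 (14, 20), activation function X5 (Tanh, SELU, LeakyReLU, ReLU)
#' and optimizer X6 (SGD, Adam) — 2*2*4*2*4*2 = 256 grid points probed with
#' just 12 uniform-design runs.
#'
#' @return A named list of six [factor_spec()]s.
#' @export
default_space <- function() {
  list(
    X1 = factor_spec("X1", c(8L, 16L)),
    X2 = factor_spec("X2", c(3L, 5L)),
    X3 = factor_spec("X3", c(4L, 8L, 16L, 32L)),
    X4 = factor_spec("X4", c(14L, 20L)),
    X5 = factor_spec("X5", c("Tanh", "SELU", "LeakyReLU", "ReLU")),
    X6 = factor_spec("X6", c("SGD", "Adam")))
}

#' A concrete hyperparameter combination
#'
#' One candidate network configuration: the six tuned factors plus the fixed
#' training constants — shared learning rate eta = 0.001, Adam epsilon =
#' 1e-8, SELU scale 1.050 and alpha 1.6732, LeakyReLU negative slope lambda
#' = 0.03. Constants can be overridden but default to these values.
#'
#' @param n_kernels,kernel_size,pooling_size,n_layers,activation,optimizer
#'   values of X1..X6.
#' @param eta,adam_epsilon,selu_scale,selu_alpha,leaky_slope fixed training
#'   constants.
#' @return An object of class `candidate_config`.
#' @export
candidate_config <- function(n_kernels, kernel_size, pooling_size, n_layers,
                             activation, optimizer,
                             eta = 0.001, adam_epsilon = 1e-8,
                             selu_scale = 1.050, selu_alpha = 1.6732,
                             leaky_slope = 0.03) {
  activation <- match.arg(activation, c("Tanh", "SELU", "LeakyReLU", "ReLU"))
  optimizer <- match.arg(optimizer, c("SGD", "Adam"))
  structure(list(
    n_kernels = as.integer(n_kernels), kernel_size = as.integer(kernel_size),
    pooling_size = as.integer(pooling_size), n_layers = as.integer(n_layers),
    activation = activation, optimizer = optimizer,
    eta = eta, adam_epsilon = adam_epsilon, selu_scale = selu_scale,
    selu_alpha = selu_alpha, leaky_slope = leaky_slope),
    class = "candidate_config")
}

#' Realize a mixed-level design into candidate configurations
#'
#' Maps each row of level indices onto the concrete factor levels of `space`
#' (factor order X1..X6) and populates the fixed training constants.
#'
#' @param design a `mixed_level_design` whose per-column level counts match
#'   the level counts of `space`.
#' @param space a list of six [factor_spec()]s as from [default_space()].
#' @param ... constant overrides passed on to [candidate_config()].
#' @return A list of `candidate_config`, one per design run.
#' @export
realize <- function(design, space = default_space(), ...) {
  stopifnot(inherits(design, "mixed_level_design"))
  if (length(space) != length(design$levels_per_factor))
    stop("design and space disagree on the number of factors", call. = FALSE)
  for (j in seq_along(space)) {
    if (length(space[[j]]$levels) != design$levels_per_factor[j])
      stop(sprintf(
        "factor %s: design has %d levels but the space defines %d",
        space[[j]]$name, design$levels_per_factor[j],
        length(space[[j]]$levels)), call. = FALSE)
  }
  lapply(seq_len(design$n_runs), function(r) {
    lv <- design$matrix[r, ]
    candidate_config(
      n_kernels    = space[[1L]]$levels[lv[1L]],
      kernel_size  = space[[2L]]$levels[lv[2L]],
      pooling_size = space[[3L]]$levels[lv[3L]],
      n_layers     = space[[4L]]$levels[lv[4L]],
      activation   = space[[5L]]$levels[lv[5L]],
      optimizer    = space[[6L]]$levels[lv[6L]], ...)
  })
}

#' Write / read a candidate configuration as YAML
#'
#' Lossless round-trip of a [candidate_config()] (factors plus constants)
#' through a small YAML schema with `factors:` and `constants:` blocks.
#'
#' @param config a `candidate_config`.
#' @param path file path.
#' @return `path` invisibly for the writer; a `candidate_config` for the
#'   reader.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "candidate_config"))
  obj <- list(
    factors = list(
      n_kernels = config$n_kernels, kernel_size = config$kernel_size,
      pooling_size = config$pooling_size, n_layers = config$n_layers,
      activation = config$activation, optimizer = config$optimizer),
    constants = list(
      eta = config$eta, adam_epsilon = config$adam_epsilon,
      selu_scale = config$selu_scale, selu_alpha = config$selu_alpha,
      leaky_slope = config$leaky_slope))
  writeLines(yaml::as.yaml(obj, precision = 17L), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(candidate_config, c(obj$factors, obj$constants))
}

#' @export
print.candidate_config <- function(x, ...) {
  cat(sprintf(
    "candidate_config: %d kernels, size %d, pooling %d, %d layers, %s, %s\n",
    x$n_kernels, x$kernel_size, x$pooling_size, x$n_layers, x$activation,
    x$optimizer))
  cat(sprintf("  eta=%g, adam_epsilon=%g, selu=(%g, %g), leaky_slope=%g\n",
              x$eta, x$adam_epsilon, x$selu_scale, x$selu_alpha,
              x$leaky_slope))
  invisible(x)
}
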