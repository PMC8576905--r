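#' Labeled grayscale image set
#'
#' Container for a classification dataset: a list of `H x W` intensity
#' matrices with values in `[0, 1]` and a parallel label vector over a fixed
#' class alphabet.
#'
#' @param images list of numeric matrices in `[0, 1]`.
#' @param labels character vector, one label per image.
#' @param class_labels ordered class alphabet (default: sorted unique
#'   labels).
#' @param seed integer recorded for provenance.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels,
                              class_labels = sort(unique(labels)),
                              seed = NA_integer_) {
  if (length(images) != length(labels))
    stop("'images' and 'labels' must have equal length", call. = FALSE)
  if (length(labels) && !all(labels %in% class_labels))
    stop("labels outside the class alphabet", call. = FALSE)
  structure(list(images = images, labels = as.character(labels),
                 class_labels = class_labels, seed = as.integer(seed)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled_image_set: %d images (%s)\n", length(x$images),
              paste(sprintf("%s=%d", x$class_labels,
                            tabulate(factor(x$labels, x$class_labels),
                                     length(x$class_labels))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) length(x$images)

subset_image_set <- function(set, idx) {
  labeled_image_set(set$images[idx], set$labels[idx], set$class_labels,
                    set$seed)
}

#' Generate a synthetic four-class OCT-like image task
#'
#' Emulates the qualitative morphology of retinal optical-coherence-
#' tomography B-scans for the four classes CNV, DME, DRUSEN and NORMAL.
#' Every image is a smooth pair of bright horizontal retinal bands on a dark
#' background, plus class-specific structure:
#' \describe{
#'   \item{NORMAL}{bands only;}
#'   \item{DRUSEN}{one-signed low-frequency sinusoidal bumps that push the
#'     upper band boundary downwards (drusen deposits);}
#'   \item{DME}{dark elliptical voids punched into the band region (edema
#'     fluid);}
#'   \item{CNV}{a bright blob beneath the lower band (neovascular lesion).}
#' }
#' Class structure is scaled by `separation` and the image is finished with
#' multiplicative speckle of amplitude `noise_level`, then clipped to
#' `[0, 1]`. The output is a pure function of the arguments: the same
#' parameters always reproduce pixel-identical images.
#'
#' The generator encodes learnable class signal, not speckle physics: it is
#' meant to exercise the tuning framework, not to simulate clinical OCT.
#'
#' @param n_per_class integer vector of 4 class counts (CNV, DME, DRUSEN,
#'   NORMAL); a single number is recycled.
#' @param image_size `(height, width)`, each at least 16.
#' @param noise_level speckle amplitude (standard deviation of the
#'   multiplicative perturbation), `>= 0`.
#' @param separation class-signal amplitude in `[0, 1]`; 0 makes all classes
#'   identical in distribution.
#' @param seed integer seed; fully determines the output.
#' @return A [labeled_image_set()] with alphabet
#'   `c("CNV", "DME", "DRUSEN", "NORMAL")`.
#' @export
generate_oct_like <- function(n_per_class = 100L, image_size = c(64L, 64L),
                              noise_level = 0.1, separation = 0.8,
                              seed = 1L) {
  classes <- c("CNV", "DME", "DRUSEN", "NORMAL")
  n_per_class <- as.integer(rep(n_per_class, length.out = 4L))
  if (any(n_per_class < 0L)) stop("negative class count", call. = FALSE)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 16L))
    stop("'image_size' must be (height, width), each >= 16", call. = FALSE)
  if (noise_level < 0) stop("'noise_level' must be >= 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  images <- vector("list", sum(n_per_class))
  labels <- rep(classes, times = n_per_class)
  for (i in seq_along(labels))
    images[[i]] <- oct_like_image(labels[i], image_size[1L], image_size[2L],
                                  noise_level, separation)
  labeled_image_set(images, labels, classes, seed = seed)
}

oct_like_image <- function(class, H, W, noise_level, separation) {
  x <- seq_len(W) / W                       # lateral position in [0, 1]
  Y <- matrix(seq_len(H), H, W)             # row index grid
  jit <- function(a) stats::runif(1L, -a, a)

  b1 <- H * (0.38 + jit(0.015))             # upper band center (rows)
  b2 <- H * (0.62 + jit(0.015))             # lower band center
  w1 <- H * 0.085 * (1 + jit(0.10))
  w2 <- H * 0.060 * (1 + jit(0.10))
  a1 <- 0.55 * (1 + jit(0.08))
  a2 <- 0.40 * (1 + jit(0.08))
  bg <- 0.12 + jit(0.02)

  boundary <- numeric(W)                    # class-dependent band deflection
  if (class == "DRUSEN") {
    f <- stats::runif(1L, 2, 3)
    ph <- stats::runif(1L, 0, 2 * pi)
    # one-signed squared-sine bumps: deposits push the band downwards
    boundary <- separation * H * 0.16 * pmax(sin(2 * pi * f * x + ph), 0)^2
  }
  B1 <- matrix(b1 + boundary, H, W, byrow = TRUE)
  B2 <- matrix(b2 + 0.5 * boundary, H, W, byrow = TRUE)
  img <- bg + a1 * exp(-(Y - B1)^2 / (2 * w1^2)) +
              a2 * exp(-(Y - B2)^2 / (2 * w2^2))

  Xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (class == "DME") {
    for (v in seq_len(3L)) {                # dark elliptical voids in band 1
      cx <- W * (0.2 + 0.3 * (v - 1) + jit(0.08))
      cy <- b1 + jit(0.4 * w1)
      rx <- W * stats::runif(1L, 0.08, 0.12)
      ry <- w1 * stats::runif(1L, 0.8, 1.2)
      d2 <- ((Xg - cx) / rx)^2 + ((Y - cy) / ry)^2
      img <- img * (1 - separation * 0.9 * exp(-d2))
    }
  } else if (class == "CNV") {              # bright sub-band blob
    cx <- W * (0.5 + jit(0.12))
    cy <- H * (0.80 + jit(0.02))
    rx <- W * stats::runif(1L, 0.14, 0.20)
    ry <- H * stats::runif(1L, 0.06, 0.09)
    d2 <- ((Xg - cx) / rx)^2 + ((Y - cy) / ry)^2
    img <- img + separation * 0.65 * exp(-d2)
  }

  if (noise_level > 0)
    img <- img * (1 + noise_level * matrix(stats::rnorm(H * W), H, W))
  # display normalization: affine rescale of the speckled image onto [0, 1]
  img <- img - min(img)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}

# Save/restore the global RNG state so generators are pure functions.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Scaled synthetic datasets with the reference class structure
#'
#' Builds a modeling pool with the imbalanced class proportions of the
#' reference OCT study (37205 CNV, 11348 DME, 8616 DRUSEN, 26315 NORMAL)
#' scaled by `scale` and rounded, plus a balanced test set of `round(242 *
#' scale)` images per class. The two sets are generated from distinct seed
#' streams and are disjoint by construction.
#'
#' @param scale scale factor in `(0, 1]`; every scaled count must round to
#'   at least 1.
#' @param seed integer seed.
#' @param image_size,noise_level,separation forwarded to
#'   [generate_oct_like()].
#' @return `list(modeling =, test =)` of two [labeled_image_set()]s.
#' @export
mimic_reference_counts <- function(scale, seed = 1L,
                                   image_size = c(64L, 64L),
                                   noise_level = 0.1, separation = 0.8) {
  if (scale <= 0 || scale > 1) stop("'scale' must be in (0, 1]",
                                    call. = FALSE)
  pool_n <- round(c(37205, 11348, 8616, 26315) * scale)
  test_n <- rep(round(242 * scale), 4L)
  if (any(pool_n < 1) || any(test_n < 1))
    stop("'scale' too small: a class count rounded to zero", call. = FALSE)
  seed <- as.integer(seed)
  list(
    modeling = generate_oct_like(pool_n, image_size, noise_level, separation,
                                 seed = seed),
    test = generate_oct_like(test_n, image_size, noise_level, separation,
                             seed = seed + 104729L))
}

#' Write / read a folder-per-class image dataset
#'
#' The on-disk layout is one subdirectory per class containing grayscale
#' PNG (canonical, 8-bit, lossless round-trip) or JPEG images. Intensities
#' are quantized as `round(v * 255)` on write. Reading sorts class
#' directories lexicographically into the class alphabet and file names
#' lexicographically within a class, so the order is reproducible.
#'
#' @param set a [labeled_image_set()].
#' @param path dataset directory.
#' @param format `"png"` (default) or `"jpeg"`.
#' @return `path` invisibly for the writer; a `labeled_image_set` for the
#'   reader.
#' @export
write_image_folder <- function(set, path, format = c("png", "jpeg")) {
  format <- match.arg(format)
  stopifnot(inherits(set, "labeled_image_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  idx_in_class <- stats::ave(seq_along(set$labels), set$labels,
                             FUN = seq_along)
  for (cl in set$class_labels)
    dir.create(file.path(path, cl), showWarnings = FALSE)
  for (i in seq_along(set$images)) {
    img <- round(set$images[[i]] * 255) / 255
    f <- file.path(path, set$labels[i],
                   sprintf("img_%05d.%s", idx_in_class[i], format))
    if (format == "png") {
      png::writePNG(img, f)
    } else {
      EBImage::writeImage(EBImage::Image(t(img)), f, quality = 98L)
    }
  }
  invisible(path)
}

#' @rdname write_image_folder
#' @export
read_image_folder <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path),
                              call. = FALSE)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories found", call. = FALSE)
  images <- list(); labels <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) {
      warning(sprintf("class folder '%s' is empty", cl), call. = FALSE)
      next
    }
    for (f in files) {
      img <- tryCatch(read_gray_image(f),
                      error = function(e) stop(sprintf(
                        "unreadable image file: %s (%s)", f,
                        conditionMessage(e)), call. = FALSE))
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
    }
  }
  labeled_image_set(images, labels, class_labels = classes)
}

# Returns an H x W matrix in [0,1]; PNG via the png package (rows = height
# natively), JPEG via EBImage (stored width-major, hence the transpose).
read_gray_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    t(a)
  }
}

# Cheap content fingerprint used for disjointness checks between datasets.
image_fingerprints <- function(set) {
  vapply(set$images, function(img) {
    v <- as.numeric(img)
    k <- seq_along(v)
    paste(format(c(sum(v), sum(v * k), sum(v * k^2)), digits = 12),
          collapse = "|")
  }, character(1L))
}
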