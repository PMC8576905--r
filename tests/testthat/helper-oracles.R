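# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Nearest-centroid classification accuracy on raw pixels (train-on-self).
nearest_centroid_accuracy <- function(set) {
  cls <- set$class_labels
  X <- t(vapply(set$images, as.numeric,
                numeric(length(set$images[[1]]))))
  cent <- vapply(cls,
                 function(cl) colMeans(X[set$labels == cl, , drop = FALSE]),
                 numeric(ncol(X)))
  pred <- cls[apply(X, 1L, function(v) which.min(colSums((cent - v)^2)))]
  mean(pred == set$labels)
}

# Straight-from-the-formula centered L2 discrepancy (double loop), kept
# independent of the package's vectorized implementation.
cd2_reference <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); s <- ncol(x)
  t1 <- (13 / 12)^s
  t2 <- 0
  for (i in seq_len(n)) {
    pr <- 1
    for (j in seq_len(s)) {
      d <- abs(x[i, j] - 0.5)
      pr <- pr * (1 + d / 2 - d^2 / 2)
    }
    t2 <- t2 + pr
  }
  t3 <- 0
  for (i in seq_len(n)) for (l in seq_len(n)) {
    pr <- 1
    for (j in seq_len(s)) {
      di <- abs(x[i, j] - 0.5); dl <- abs(x[l, j] - 0.5)
      pr <- pr * (1 + di / 2 + dl / 2 - abs(x[i, j] - x[l, j]) / 2)
    }
    t3 <- t3 + pr
  }
  sqrt(t1 - 2 * t2 / n + t3 / n^2)
}

# Numeric-integration oracle for the centered L2 discrepancy: sum over all
# non-empty coordinate projections u of the integral of the squared local
# discrepancy of the box anchored at the corner of the cube nearest to x.
# The integrand is piecewise polynomial on the cell grid cut at the point
# coordinates and 0.5, so per-cell Gauss-Legendre quadrature is exact.
cd2_numeric <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); s <- ncol(x)
  # 4-point Gauss-Legendre on [-1, 1]
  gp <- c(-0.861136311594053, -0.339981043584856,
          0.339981043584856, 0.861136311594053)
  gw <- c(0.347854845137454, 0.652145154862546,
          0.652145154862546, 0.347854845137454)
  disc2 <- function(pt, cols) {
    a <- ifelse(pt <= 0.5, 0, 1)
    lo <- pmin(pt, a); hi <- pmax(pt, a)
    inside <- rep(TRUE, n)
    for (jj in seq_along(cols))
      inside <- inside & x[, cols[jj]] >= lo[jj] & x[, cols[jj]] <= hi[jj]
    (sum(inside) / n - prod(hi - lo))^2
  }
  total <- 0
  for (m in seq_len(s)) {
    for (cols in utils::combn(s, m, simplify = FALSE)) {
      brk <- lapply(cols, function(j) sort(unique(c(0, 0.5, 1, x[, j]))))
      pieces <- lapply(brk, function(b)
        cbind(b[-length(b)], b[-1L]))
      idx <- do.call(expand.grid, lapply(pieces, function(p) seq_len(nrow(p))))
      for (r in seq_len(nrow(idx))) {
        lods <- vapply(seq_len(m), function(jj)
          pieces[[jj]][idx[r, jj], 1L], numeric(1L))
        hids <- vapply(seq_len(m), function(jj)
          pieces[[jj]][idx[r, jj], 2L], numeric(1L))
        h <- (hids - lods) / 2; c0 <- (hids + lods) / 2
        if (any(h == 0)) next
        nodes <- do.call(expand.grid, rep(list(seq_along(gp)), m))
        for (q in seq_len(nrow(nodes))) {
          ni <- as.integer(nodes[q, ])
          pt <- c0 + h * gp[ni]
          w <- prod(gw[ni] * h)
          total <- total + w * disc2(pt, cols)
        }
      }
    }
  }
  sqrt(total)
}

# Independent good-lattice column construction for cross-checks.
glp_columns_reference <- function(n_runs) {
  modulus <- if (n_runs %% 2 == 0) n_runs + 1L else n_runs
  hs <- Filter(function(h) {
    a <- h; b <- modulus
    while (b) { t <- b; b <- a %% b; a <- t }
    a == 1
  }, seq_len(modulus - 1L))
  cols <- sapply(hs, function(h) {
    u <- (seq_len(modulus) * h) %% modulus
    u[u == 0] <- modulus
    u[seq_len(n_runs)]
  })
  storage.mode(cols) <- "integer"
  list(generators = hs, columns = cols)
}

# Small fast image set for tests that only exercise plumbing, not learning.
tiny_image_set <- function(n_per_class = 6, size = 16, seed = 1) {
  generate_oct_like(n_per_class, c(size, size), noise_level = 0.1,
                    separation = 0.8, seed = seed)
}

# A trainer-shaped stub whose "model" predicts perfectly on any set.
perfect_stub_trainer <- function() {
  function(config, train_set, val_set, protocol, info = NULL) {
    list(train_accuracy = 1, validation_accuracy = 1,
         model = function(set) set$labels)
  }
}
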