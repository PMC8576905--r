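test_that("every generated layout column is a permutation of 1..n_runs", {
  for (n in 2:13) {
    capacity <- length(glp_columns_reference(n)$generators)
    for (s in seq_len(min(4L, capacity))) {
      layout <- good_lattice_layout(n, s)
      expect_identical(dim(layout$matrix), c(n, as.integer(s)))
      for (j in seq_len(s))
        expect_identical(sort(layout$matrix[, j]), seq_len(n),
                         info = sprintf("n=%d s=%d col=%d", n, s, j))
    }
  }
})

test_that("the 2-run single-factor layout is the column (1, 2)", {
  expect_identical(good_lattice_layout(2, 1)$matrix,
                   matrix(1:2, ncol = 1))
})

test_that("even-n layouts come from the odd (n+1)-run lattice minus its all-max row", {
  for (n in c(2L, 6L, 10L, 12L)) {
    layout <- good_lattice_layout(n, 2)
    modulus <- n + 1L
    for (j in seq_along(layout$generators)) {
      h <- layout$generators[j]
      u <- (seq_len(modulus) * h) %% modulus
      u[u == 0] <- modulus
      expect_identical(u[modulus], modulus)   # deleted row is all-max
      expect_identical(layout$matrix[, j], u[seq_len(n)])
    }
  }
})

test_that("the 5x2 layout minimizes centered L2 discrepancy over all column pairs", {
  ref <- glp_columns_reference(5)
  pairs <- utils::combn(ncol(ref$columns), 2, simplify = FALSE)
  scores <- vapply(pairs, function(jj)
    cd2_reference((ref$columns[, jj] - 0.5) / 5), numeric(1))
  best <- pairs[[which.min(scores)]]
  layout <- good_lattice_layout(5, 2)
  expect_identical(layout$matrix, ref$columns[, best])
  expect_equal(centered_l2_discrepancy(layout), min(scores),
               tolerance = 1e-12)
})

test_that("capacity and domain errors are explicit", {
  expect_error(good_lattice_layout(1, 1), "n_runs")
  expect_error(good_lattice_layout(5, 10), "capacity")
  # phi(9) = 6 candidate columns for the 9-run lattice
  expect_error(good_lattice_layout(9, 7), "at most 6")
})

test_that("collapsing with m_j = n is the identity", {
  layout <- good_lattice_layout(6, 2)
  d <- collapse_levels(layout, c(6, 6))
  expect_identical(d$matrix, layout$matrix)
})

test_that("the ceiling rule halves 12 levels into balanced 2-level columns", {
  layout <- good_lattice_layout(12, 3)
  d <- collapse_levels(layout, c(2, 2, 2))
  for (j in 1:3) {
    expect_identical(d$matrix[, j],
                     ifelse(layout$matrix[, j] <= 6, 1L, 2L))
    expect_identical(tabulate(d$matrix[, j], 2L), c(6L, 6L))
  }
})

test_that("collapsing is balanced for every divisor level count", {
  layout <- good_lattice_layout(12, 4)
  for (m in c(2L, 3L, 4L, 6L, 12L)) {
    d <- collapse_levels(layout, rep(m, 4))
    for (j in 1:4)
      expect_identical(tabulate(d$matrix[, j], m),
                       rep(12L %/% m, m))
  }
})

test_that("non-divisor target level counts raise an error naming the column", {
  layout <- good_lattice_layout(12, 3)
  expect_error(collapse_levels(layout, c(2, 5, 2)), "column 2")
})

test_that("discrepancy is invariant under row reordering", {
  layout <- good_lattice_layout(8, 3)
  d1 <- collapse_levels(layout, c(2, 4, 8))
  shuffled <- d1
  shuffled$matrix <- d1$matrix[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  expect_equal(centered_l2_discrepancy(d1),
               centered_l2_discrepancy(shuffled), tolerance = 1e-14)
})

test_that("closed-form discrepancy matches numeric integration of its definition", {
  # single point at 0.5: 1-run, 1-level design
  one <- collapse_levels(good_lattice_layout(2, 1), 1)
  one$matrix <- one$matrix[1L, , drop = FALSE]; one$n_runs <- 1L
  expect_equal(centered_l2_discrepancy(one), cd2_numeric(matrix(0.5)),
               tolerance = 1e-6)
  cases <- list(good_lattice_layout(2, 1), good_lattice_layout(3, 2),
                good_lattice_layout(4, 2),
                collapse_levels(good_lattice_layout(4, 2), c(2, 2)))
  for (d in cases) {
    x <- if (inherits(d, "uniform_layout")) (d$matrix - 0.5) / d$n_runs
         else sweep(d$matrix - 0.5, 2, d$levels_per_factor, `/`)
    expect_equal(centered_l2_discrepancy(d), cd2_numeric(x),
                 tolerance = 1e-6)
  }
})

test_that("a spread 2-run design beats the degenerate repeated-point design", {
  spread <- collapse_levels(good_lattice_layout(2, 1), 2)
  degen <- spread
  degen$matrix <- matrix(c(1L, 1L), ncol = 1)
  expect_lt(centered_l2_discrepancy(spread),
            centered_l2_discrepancy(degen))
})

test_that("the reference design matches its published assignments and balance", {
  d <- reference_design()
  expect_identical(d$n_runs, 12L)
  expect_identical(d$levels_per_factor, c(2L, 2L, 4L, 2L, 4L, 2L))
  # every 4-level factor has each level 3 times, every 2-level factor 6 times
  for (j in seq_len(6))
    expect_identical(tabulate(d$matrix[, j], d$levels_per_factor[j]),
                     rep(12L %/% d$levels_per_factor[j],
                         d$levels_per_factor[j]))
  cfgs <- realize(d, default_space())
  r4 <- cfgs[[4]]
  expect_identical(c(r4$n_kernels, r4$kernel_size, r4$pooling_size,
                     r4$n_layers), c(16L, 5L, 16L, 20L))
  expect_identical(r4$activation, "SELU")
  expect_identical(r4$optimizer, "SGD")
  r1 <- cfgs[[1]]
  expect_identical(c(r1$n_kernels, r1$kernel_size, r1$pooling_size,
                     r1$n_layers), c(8L, 5L, 8L, 20L))
  expect_identical(r1$activation, "Tanh")
  expect_identical(r1$optimizer, "Adam")
  # activation column: each function appears exactly 3 times
  acts <- vapply(cfgs, `[[`, character(1), "activation")
  counts <- table(factor(acts, c("Tanh", "SELU", "LeakyReLU", "ReLU")))
  expect_identical(as.integer(counts), rep(3L, 4))
})

test_that("design CSV writing round-trips bit-identically", {
  d <- reference_design()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_design_csv(d, f1)
  d2 <- read_design_csv(f1, levels_per_factor = d$levels_per_factor)
  expect_identical(d2$matrix, d$matrix)
  write_design_csv(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("realized design CSV holds concrete level values", {
  f <- tempfile(fileext = ".csv")
  write_design_csv(reference_design(), f, space = default_space())
  lines <- readLines(f)
  expect_identical(lines[1], "run,X1,X2,X3,X4,X5,X6")
  expect_identical(lines[5], "4,16,5,16,20,SELU,SGD")
  expect_identical(lines[2], "1,8,5,8,20,Tanh,Adam")
})
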