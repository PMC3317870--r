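test_that("lattice contiguity matches grid geometry", {
  w <- build_lattice_weights(1, 2, "rook")
  expect_equal(w$neighbors, list(2L, 1L))

  w <- build_lattice_weights(3, 3, "rook")
  deg <- lengths(w$neighbors)
  expect_equal(deg[5], 4L)                     # centre
  expect_equal(unname(deg[c(1, 3, 7, 9)]), rep(2L, 4))  # corners

  wq <- build_lattice_weights(3, 3, "queen")
  expect_equal(lengths(wq$neighbors)[5], 8L)

  # brute-force pairwise adjacency scan (Chebyshev distance 1)
  cells <- expand.grid(r = 1:3, c = 1:3)
  cells <- cells[order(cells$r, cells$c), ]
  brute <- 0L
  for (i in 1:8) for (j in (i + 1):9) {
    if (max(abs(cells$r[i] - cells$r[j]), abs(cells$c[i] - cells$c[j])) == 1)
      brute <- brute + 1L
  }
  expect_equal(sum(lengths(wq$neighbors)) %/% 2L, brute)

  expect_error(build_lattice_weights(0, 3), "positive")
  expect_error(build_lattice_weights(1, 1), "at least 2")
})

test_that("row standardization yields unit row sums and handles islands", {
  w <- row_standardize(build_lattice_weights(1, 3, "rook"))
  W <- as.matrix(weights_matrix(w))
  expect_equal(W[2, ], c(`1` = 0.5, `2` = 0, `3` = 0.5))

  ws <- rook3()
  expect_true(ws$standardized)
  expect_equal(unname(Matrix::rowSums(weights_matrix(ws))), rep(1, 9),
               tolerance = 1e-12)

  # unit 3 is an island: kept with an all-zero row, never division by zero
  wi <- new_spatial_weights(list(2L, 1L, integer(0)),
                            list(1, 1, numeric(0)), c("a", "b", "c"))
  expect_warning(wsi <- row_standardize(wi), "no neighbours")
  expect_equal(unname(Matrix::rowSums(weights_matrix(wsi))), c(1, 1, 0))
  expect_warning(lag <- spatial_lag(wsi, c(1, 2, 3)), "island")
  expect_equal(lag, c(2, 1, 0))
})

test_that("spatial lag is the neighbour average", {
  w12 <- row_standardize(build_lattice_weights(1, 2))
  expect_equal(spatial_lag(w12, c(3, 7)), c(7, 3))

  ws <- rook3()
  expect_equal(spatial_lag(ws, rep(4.2, 9)), rep(4.2, 9), tolerance = 1e-14)

  x <- withr::with_seed(1, rnorm(9))
  got <- spatial_lag(ws, x)
  oracle <- vapply(seq_len(9), function(i) mean(x[ws$neighbors[[i]]]),
                   numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(spatial_lag(ws, 1:4), "length")
  expect_error(spatial_lag(build_lattice_weights(3, 3), x), "standardized")
})

test_that("spatial lag agrees with the dense matrix product on larger lattices", {
  for (dims in list(c(4, 7), c(20, 20))) {
    w <- row_standardize(build_lattice_weights(dims[1], dims[2]))
    x <- withr::with_seed(dims[1] * 100 + dims[2], rnorm(w$n))
    expect_equal(spatial_lag(w, x),
                 as.numeric(as.matrix(weights_matrix(w)) %*% x),
                 tolerance = 1e-12)
  }
})

test_that("the cached spectrum is the real spectrum of the standardized matrix", {
  w12 <- row_standardize(build_lattice_weights(1, 2))
  expect_equal(sort(eigenvalues(w12)), c(-1, 1), tolerance = 1e-12)

  ws <- rook3()
  ev <- eigenvalues(ws)
  expect_equal(max(ev), 1, tolerance = 1e-10)      # row sums are 1
  expect_equal(sum(ev), 0, tolerance = 1e-10)      # zero diagonal => trace 0

  # similarity argument: the general (non-symmetric) eigensolver agrees and
  # reports negligible imaginary parts
  w55 <- row_standardize(build_lattice_weights(5, 5))
  gen <- eigen(as.matrix(weights_matrix(w55)), only.values = TRUE)$values
  expect_lt(max(abs(Im(gen))), 1e-8)
  expect_equal(sort(Re(gen)), sort(eigenvalues(w55)), tolerance = 1e-8)

  # power-iteration oracle for the leading eigenvalue of a connected lattice
  W <- as.matrix(weights_matrix(w55))
  v <- rep(1 / sqrt(25), 25)
  for (i in 1:200) {
    v2 <- W %*% v + v          # shift keeps the iteration stable
    v <- v2 / sqrt(sum(v2^2))
  }
  lead <- as.numeric(t(v) %*% W %*% v)
  expect_equal(lead, max(eigenvalues(w55)), tolerance = 1e-8)
  expect_equal(lead, 1, tolerance = 1e-8)
})

test_that("GAL files round-trip and malformed input is rejected by line", {
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("2", "a 1", "b", "b 1", "a"), path)
  w <- read_gal(path)
  expect_equal(w$n, 2L)
  expect_equal(w$ids, c("a", "b"))
  expect_equal(w$neighbors, list(2L, 1L))

  wq <- build_lattice_weights(3, 3, "queen")
  write_gal(wq, path)
  back <- read_gal(path)
  pairs <- function(w) {
    p <- do.call(rbind, lapply(seq_len(w$n), function(i)
      cbind(w$ids[i], w$ids[w$neighbors[[i]]])))
    sort(apply(p, 1, function(r) paste(sort(r), collapse = "-")))
  }
  expect_equal(pairs(back), pairs(wq))
  expect_equal(length(unique(pairs(back))), 20L)   # 12 rook + 8 diagonal links

  writeLines(c("2", "a 1", "z", "b 1", "a"), path)
  expect_error(read_gal(path), "unknown neighbour id 'z'")
  writeLines(c("banana"), path)
  expect_error(read_gal(path), "malformed GAL header")
  writeLines(c("2", "a 1", "b", "b 0", ""), path)
  expect_error(read_gal(path), "asymmetric")
})

test_that("weights invariants are enforced at construction", {
  expect_error(new_spatial_weights(list(1L, integer(0)), list(1, numeric(0)),
                                   c("a", "b")), "itself")
  expect_error(new_spatial_weights(list(2L, 1L), list(-1, 1), c("a", "b")),
               "negative")
  expect_error(new_spatial_weights(list(2L, integer(0)), list(1, numeric(0)),
                                   c("a", "b")), "asymmetric")
})
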