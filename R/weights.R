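#' Spatial weights objects
#'
#' A `spatial_weights` object stores an N x N neighbourhood structure as
#' per-unit neighbour lists with nonnegative pairwise weights.  The diagonal is
#' always zero (no unit is its own neighbour) and the underlying neighbour
#' *relation* is symmetric, as befits contiguity.  After [row_standardize()]
#' every row with at least one neighbour sums to one, so `W x` is the
#' neighbour average of `x` -- the "spatial lag" used both for spatially
#' lagged covariates and for the spatial error / lag processes.
#'
#' The spectrum of the row-standardized matrix is computed lazily and cached;
#' it feeds the eigenvalue form of the log-determinant in the concentrated
#' likelihoods.
#'
#' @param neighbors list of integer vectors, one per unit, giving neighbour
#'   indices.
#' @param weights list of numeric vectors aligned with `neighbors`.
#' @param ids character labels for the units; must match the panel's region
#'   ids when the two are used together.
#' @param standardized logical; `TRUE` when rows have been normalized to sum
#'   to one.
#' @return An object of class `spatial_weights` with fields `n`, `ids`,
#'   `neighbors`, `weights`, `standardized`.
#' @seealso [build_lattice_weights()], [row_standardize()], [spatial_lag()],
#'   [read_gal()]
#' @export
new_spatial_weights <- function(neighbors, weights, ids,
                                standardized = FALSE) {
  n <- length(neighbors)
  if (length(weights) != n || length(ids) != n)
    stop("`neighbors`, `weights` and `ids` must have equal length",
         call. = FALSE)
  w <- structure(
    list(
      n = n,
      ids = as.character(ids),
      neighbors = lapply(neighbors, as.integer),
      weights = lapply(weights, as.numeric),
      standardized = isTRUE(standardized),
      cache = new.env(parent = emptyenv())
    ),
    class = "spatial_weights"
  )
  validate_spatial_weights(w)
  w
}

validate_spatial_weights <- function(w) {
  if (w$n < 2L)
    stop("a spatial weights object needs at least 2 units", call. = FALSE)
  if (anyDuplicated(w$ids))
    stop("duplicated unit ids in spatial weights", call. = FALSE)
  for (i in seq_len(w$n)) {
    nb <- w$neighbors[[i]]
    if (length(nb) != length(w$weights[[i]]))
      stop(sprintf("unit '%s': neighbour and weight lists differ in length",
                   w$ids[i]), call. = FALSE)
    if (any(nb < 1L | nb > w$n))
      stop(sprintf("unit '%s': neighbour index out of range", w$ids[i]),
           call. = FALSE)
    if (any(nb == i))
      stop(sprintf("unit '%s' lists itself as a neighbour", w$ids[i]),
           call. = FALSE)
    if (anyDuplicated(nb))
      stop(sprintf("unit '%s' lists a neighbour twice", w$ids[i]),
           call. = FALSE)
    if (any(w$weights[[i]] < 0))
      stop("negative spatial weights are not allowed", call. = FALSE)
  }
  for (i in seq_len(w$n)) {
    for (j in w$neighbors[[i]]) {
      if (!(i %in% w$neighbors[[j]]))
        stop(sprintf(
          "asymmetric adjacency: unit '%s' lists '%s' but not vice versa",
          w$ids[i], w$ids[j]), call. = FALSE)
    }
  }
  invisible(w)
}

#' @export
#' @method print spatial_weights
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("Spatial weights: %d units, %d symmetric links, %s\n",
              x$n, sum(deg) %/% 2L,
              if (x$standardized) "row-standardized" else "binary"))
  cat(sprintf("  neighbours per unit: min %d, mean %.2f, max %d; islands: %d\n",
              min(deg), mean(deg), max(deg), sum(deg == 0L)))
  invisible(x)
}

#' Contiguity weights on a regular lattice
#'
#' Builds the binary contiguity matrix of a `rows` x `cols` grid.  Under the
#' rook criterion cells sharing an edge are neighbours; under queen, cells
#' sharing an edge or a corner.  Units are labelled `"1"` .. `"rows*cols"` in
#' row-major order.  The result is unstandardized; pass it through
#' [row_standardize()] before computing spatial lags.
#'
#' @param rows,cols positive integers, grid dimensions with `rows * cols >= 2`.
#' @param scheme `"rook"` (default) or `"queen"`.
#' @return An unstandardized [new_spatial_weights()] object.
#' @examples
#' w <- build_lattice_weights(3, 3, "queen")
#' lengths(w$neighbors)  # centre cell has 8 neighbours
#' @export
build_lattice_weights <- function(rows, cols, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("`rows` and `cols` must be positive integers", call. = FALSE)
  if (rows * cols < 2L)
    stop("the lattice must contain at least 2 cells", call. = FALSE)
  off <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (scheme == "queen")
    off <- c(off, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  n <- rows * cols
  neighbors <- vector("list", n)
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      i <- (r - 1L) * cols + cc
      nb <- integer(0)
      for (d in off) {
        rr <- r + d[1L]; c2 <- cc + d[2L]
        if (rr >= 1L && rr <= rows && c2 >= 1L && c2 <= cols)
          nb <- c(nb, (rr - 1L) * cols + c2)
      }
      neighbors[[i]] <- sort(nb)
    }
  }
  new_spatial_weights(
    neighbors = neighbors,
    weights = lapply(neighbors, function(nb) rep(1, length(nb))),
    ids = as.character(seq_len(n)),
    standardized = FALSE
  )
}

#' Row-standardize a spatial weights object
#'
#' Divides every nonempty row by its sum so that the spatial lag becomes a
#' simple average over the contiguous units.  Units without neighbours
#' (islands) keep an all-zero row and a warning is emitted; they are retained
#' rather than dropped so that a balanced panel stays balanced.
#'
#' @param w a `spatial_weights` object with at least one non-island unit.
#' @return A standardized `spatial_weights` object (cached spectrum reset).
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  deg <- lengths(w$neighbors)
  if (all(deg == 0L))
    stop("cannot row-standardize: every unit is an island", call. = FALSE)
  if (any(deg == 0L))
    warning(sprintf(
      "%d unit(s) have no neighbours; their rows are left all zero",
      sum(deg == 0L)), call. = FALSE)
  weights <- lapply(w$weights, function(v) {
    s <- sum(v)
    if (s > 0) v / s else v
  })
  new_spatial_weights(w$neighbors, weights, w$ids, standardized = TRUE)
}

#' Dense or sparse matrix form of a spatial weights object
#'
#' @param w a `spatial_weights` object.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a base matrix.
#' @return The N x N weight matrix with unit ids as dimnames.
#' @export
weights_matrix <- function(w, sparse = TRUE) {
  stopifnot(inherits(w, "spatial_weights"))
  key <- if (sparse) "W_sparse" else "W_dense"
  hit <- w$cache[[key]]
  if (!is.null(hit)) return(hit)
  deg <- lengths(w$neighbors)
  i <- rep.int(seq_len(w$n), deg)
  j <- unlist(w$neighbors, use.names = FALSE)
  x <- unlist(w$weights, use.names = FALSE)
  if (length(j) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(w$n, w$n),
                              dimnames = list(w$ids, w$ids))
  } else {
    m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(w$n, w$n),
                              dimnames = list(w$ids, w$ids))
  }
  if (!sparse) m <- as.matrix(m)
  w$cache[[key]] <- m
  m
}

#' Spatial lag (neighbour average) of a vector
#'
#' For row-standardized weights, element i of `W x` is the mean of `x` over
#' the neighbours of unit i -- the neighbour average used for spatially
#' lagged covariates.  Island rows return 0 with a warning.
#'
#' @param w a row-standardized `spatial_weights` object.
#' @param x numeric vector of length `w$n`.
#' @return Numeric vector `W x`.
#' @export
spatial_lag <- function(w, x) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!w$standardized)
    stop("`spatial_lag()` requires row-standardized weights", call. = FALSE)
  if (length(x) != w$n)
    stop(sprintf("`x` has length %d but there are %d units",
                 length(x), w$n), call. = FALSE)
  if (any(lengths(w$neighbors) == 0L))
    warning("island unit(s): their spatial lag is 0", call. = FALSE)
  as.numeric(weights_matrix(w) %*% x)
}

#' Eigenvalues of the row-standardized weight matrix
#'
#' Computed once and cached.  The row-standardized contiguity matrix
#' D^-1 A is similar to the symmetric D^-1/2 A D^-1/2, so its spectrum is
#' real; it is obtained from the symmetric form for numerical stability.
#' Island units contribute eigenvalue 0.  The spectrum underpins the
#' eigenvalue ("algebraic") form of ln|I - rho W| used by [log_jacobian()].
#'
#' @param w a row-standardized `spatial_weights` object built from binary
#'   contiguity.
#' @return Numeric vector of the n real eigenvalues, decreasing; the largest
#'   is 1 for a connected graph.
#' @export
eigenvalues <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!w$standardized)
    stop("`eigenvalues()` expects row-standardized weights", call. = FALSE)
  hit <- w$cache$spectrum
  if (!is.null(hit)) return(hit)
  deg <- lengths(w$neighbors)
  s <- ifelse(deg > 0L, 1 / sqrt(deg), 0)
  # symmetric similarity transform of D^-1 A (A binary contiguity)
  i <- rep.int(seq_len(w$n), deg)
  j <- unlist(w$neighbors, use.names = FALSE)
  x <- s[i] * s[j]
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(w$n, w$n))
  ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) > 1 + 1e-8)
    stop("eigensolver failure: spectral radius exceeds 1", call. = FALSE)
  ev <- sort(ev, decreasing = TRUE)
  w$cache$spectrum <- ev
  ev
}

# Keep the units in `keep` (integer indices), dropping all links to the rest.
subset_weights <- function(w, keep) {
  keep <- as.integer(keep)
  stopifnot(all(keep >= 1L), all(keep <= w$n), !anyDuplicated(keep))
  pos <- integer(w$n)
  pos[keep] <- seq_along(keep)
  neighbors <- vector("list", length(keep))
  weights <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    sel <- pos[w$neighbors[[i]]] > 0L
    neighbors[[k]] <- pos[w$neighbors[[i]][sel]]
    weights[[k]] <- w$weights[[i]][sel]
  }
  new_spatial_weights(neighbors, weights, w$ids[keep], standardized = FALSE)
}
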