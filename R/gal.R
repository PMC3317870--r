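#' Read a GAL-format spatial weights file
#'
#' GAL is the plain-text interchange format for contiguity weights: a header
#' line with the number of units (optionally preceded by a leading 0, as some
#' tools write), then for each unit a line `id k` followed by a line with the
#' k neighbour ids.  Weights are binary; use [row_standardize()] afterwards.
#' Malformed headers, dangling neighbour ids and asymmetric adjacency raise
#' errors naming the offending line.
#'
#' @param path path to the GAL file.
#' @return An unstandardized `spatial_weights` object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop(sprintf("%s: empty GAL file", path), call. = FALSE)
  toks <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  hd <- toks(lines[1L])
  hd <- hd[nzchar(hd)]
  n <- if (length(hd) == 1L) suppressWarnings(as.integer(hd)) else
    if (length(hd) >= 2L && hd[1L] == "0") suppressWarnings(as.integer(hd[2L])) else NA_integer_
  if (is.na(n) || n < 2L)
    stop(sprintf("%s, line 1: malformed GAL header '%s'", path, lines[1L]),
         call. = FALSE)
  ids <- character(n)
  nb_ids <- vector("list", n)
  unit_line <- integer(n)
  ln <- 1L
  for (u in seq_len(n)) {
    ln <- ln + 1L
    if (ln > length(lines))
      stop(sprintf("%s: truncated file, expected %d units", path, n),
           call. = FALSE)
    hd <- toks(lines[ln])
    if (length(hd) != 2L)
      stop(sprintf("%s, line %d: expected 'id count', got '%s'",
                   path, ln, lines[ln]), call. = FALSE)
    k <- suppressWarnings(as.integer(hd[2L]))
    if (is.na(k) || k < 0L)
      stop(sprintf("%s, line %d: bad neighbour count '%s'",
                   path, ln, hd[2L]), call. = FALSE)
    ids[u] <- hd[1L]
    unit_line[u] <- ln
    if (k > 0L) {
      ln <- ln + 1L
      if (ln > length(lines))
        stop(sprintf("%s: truncated neighbour list for unit '%s'",
                     path, ids[u]), call. = FALSE)
      nb <- toks(lines[ln])
      if (length(nb) != k)
        stop(sprintf("%s, line %d: unit '%s' declares %d neighbours but lists %d",
                     path, ln, ids[u], k, length(nb)), call. = FALSE)
      nb_ids[[u]] <- nb
    } else {
      nb_ids[[u]] <- character(0)
      # tolerate the blank neighbour line some writers emit for islands
      if (ln + 1L <= length(lines) && !nzchar(trimws(lines[ln + 1L])))
        ln <- ln + 1L
    }
  }
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicated unit id '%s'", path, ids[anyDuplicated(ids)]),
         call. = FALSE)
  idx <- seq_len(n)
  names(idx) <- ids
  neighbors <- vector("list", n)
  for (u in seq_len(n)) {
    m <- idx[nb_ids[[u]]]
    if (anyNA(m)) {
      bad <- nb_ids[[u]][is.na(m)][1L]
      stop(sprintf("%s, line %d: unknown neighbour id '%s' for unit '%s'",
                   path, unit_line[u] + 1L, bad, ids[u]), call. = FALSE)
    }
    neighbors[[u]] <- unname(m)
  }
  for (u in seq_len(n)) {
    for (v in neighbors[[u]]) {
      if (!(u %in% neighbors[[v]]))
        stop(sprintf(
          "%s, line %d: asymmetric adjacency, '%s' lists '%s' but not vice versa",
          path, unit_line[u] + 1L, ids[u], ids[v]), call. = FALSE)
    }
  }
  new_spatial_weights(
    neighbors = neighbors,
    weights = lapply(neighbors, function(nb) rep(1, length(nb))),
    ids = ids,
    standardized = FALSE
  )
}

#' Write a spatial weights object in GAL format
#'
#' Writes the neighbour structure (not the weight values -- GAL is a binary
#' contiguity format); `read_gal(write_gal(w, f))` reproduces the neighbour
#' structure exactly.
#'
#' @param w a `spatial_weights` object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  out <- character(1L + 2L * w$n)
  out[1L] <- as.character(w$n)
  k <- 2L
  for (i in seq_len(w$n)) {
    nb <- w$neighbors[[i]]
    out[k] <- sprintf("%s %d", w$ids[i], length(nb))
    out[k + 1L] <- paste(w$ids[nb], collapse = " ")
    k <- k + 2L
  }
  writeLines(out, path)
  invisible(path)
}
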