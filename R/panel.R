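#' Balanced panel container
#'
#' `panel_data` holds a balanced region x period panel in *period-major*
#' stacking: all N regions of period 1, then all N of period 2, and so on.
#' With that convention every per-period spatial operator is the block
#' diagonal I_T (x) W, applied column-block by column-block.
#'
#' @name panel_data
#' @keywords internal
NULL

new_panel_data <- function(y, X, region_ids, period_labels, outcome_name,
                           within = FALSE, means = NULL) {
  n <- length(region_ids); t <- length(period_labels)
  stopifnot(length(y) == n * t, nrow(X) == n * t)
  structure(
    list(
      n_regions = n,
      n_periods = t,
      region_ids = as.character(region_ids),
      period_labels = as.character(period_labels),
      y = as.numeric(y),
      X = X,
      covariate_names = colnames(X),
      outcome_name = outcome_name,
      region = rep.int(seq_len(n), t),
      period = rep(seq_len(t), each = n),
      within = within,
      means = means
    ),
    class = "panel_data"
  )
}

#' @export
#' @method print panel_data
print.panel_data <- function(x, ...) {
  cat(sprintf(
    "Balanced panel: %d regions x %d periods (%d rows), outcome '%s'%s\n",
    x$n_regions, x$n_periods, length(x$y), x$outcome_name,
    if (x$within) " [within-transformed]" else ""))
  cat("  periods:   ", paste(x$period_labels, collapse = ", "), "\n")
  cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a long-format table into a balanced panel
#'
#' Checks balance (every region present exactly once per period), coerces a
#' deterministic ordering (regions sorted by id, periods in `period_order` or
#' sorted), and stacks outcome and design period-major.  The same records in
#' any row order produce the identical `panel_data`.
#'
#' @param table a data.frame in long format.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names; default all
#'   numeric columns other than the id, period and outcome columns.
#' @param region_col,period_col names of the id columns (defaults
#'   `"region_id"`, `"period"`).
#' @param period_order optional character vector fixing the period ordering;
#'   must be a permutation of the periods present.
#' @return A `panel_data` object.
#' @export
validate_panel <- function(table, outcome, covariates = NULL,
                           region_col = "region_id", period_col = "period",
                           period_order = NULL) {
  stopifnot(is.data.frame(table))
  for (col in c(region_col, period_col, outcome))
    if (!col %in% names(table))
      stop(sprintf("column '%s' not found in the panel table", col),
           call. = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))],
      c(region_col, period_col, outcome))
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov))
    stop(sprintf("covariate column(s) not found: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  for (col in c(outcome, covariates))
    if (!is.numeric(table[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  if (anyNA(table[c(outcome, covariates)]))
    stop("missing values in outcome or covariates", call. = FALSE)

  rid <- as.character(table[[region_col]])
  per <- as.character(table[[period_col]])
  regions <- sort(unique(rid))
  periods <- if (is.null(period_order)) sort(unique(per)) else {
    if (!setequal(period_order, unique(per)))
      stop("`period_order` must be a permutation of the periods present",
           call. = FALSE)
    as.character(period_order)
  }
  if (length(periods) < 1L || length(regions) < 2L)
    stop("need at least 2 regions and 1 period", call. = FALSE)

  key <- paste(rid, per, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop(sprintf("duplicated (region, period) pair(s): %s",
                 paste(head(sub("\r", ", ", dup), 5L), collapse = "; ")),
         call. = FALSE)
  want <- as.vector(outer(regions, periods, paste, sep = "\r"))
  miss <- setdiff(want, key)
  if (length(miss))
    stop(sprintf("unbalanced panel, missing (region, period) pair(s): %s",
                 paste(head(sprintf("(%s)", sub("\r", ", ", miss)), 10L),
                       collapse = "; ")), call. = FALSE)

  ord <- order(match(per, periods), match(rid, regions))
  X <- as.matrix(table[ord, covariates, drop = FALSE])
  rownames(X) <- NULL
  colnames(X) <- covariates
  new_panel_data(
    y = table[[outcome]][ord],
    X = X,
    region_ids = regions,
    period_labels = periods,
    outcome_name = outcome
  )
}

#' Log-transform the panel outcome
#'
#' The infant-mortality outcome is modelled on the log scale; the natural
#' logarithm is the default, with `base` as an option (descriptive tables of
#' log-IMR in the literature are often base 10).
#'
#' @param p a `panel_data` object with strictly positive outcome.
#' @param base logarithm base (default `exp(1)`).
#' @return The panel with `y` replaced by `log(y, base)` and the outcome name
#'   prefixed `l_`.
#' @export
log_outcome <- function(p, base = exp(1)) {
  stopifnot(inherits(p, "panel_data"))
  bad <- which(p$y <= 0)
  if (length(bad)) {
    lab <- sprintf("(%s, %s)", p$region_ids[p$region[bad]],
                   p$period_labels[p$period[bad]])
    stop(sprintf("nonpositive outcome in row(s): %s",
                 paste(head(lab, 10L), collapse = "; ")), call. = FALSE)
  }
  p$y <- log(p$y, base = base)
  p$outcome_name <- paste0("l_", p$outcome_name)
  p
}

#' Append spatially lagged (neighbour-average) covariates
#'
#' For each named covariate and each period, appends the column W x_t --
#' the average of the covariate over each region's contiguous neighbours --
#' named `W*<name>`.  The weights must be row-standardized and their ids must
#' match the panel's region ids.
#'
#' @param p a `panel_data` object.
#' @param w a row-standardized `spatial_weights` object.
#' @param vars covariates to lag; default all.
#' @return The panel with `length(vars)` extra columns.
#' @export
add_spatial_lags <- function(p, w, vars = p$covariate_names) {
  stopifnot(inherits(p, "panel_data"), inherits(w, "spatial_weights"))
  if (!w$standardized)
    stop("`add_spatial_lags()` requires row-standardized weights",
         call. = FALSE)
  if (!setequal(w$ids, p$region_ids))
    stop("weight matrix ids do not match the panel's region ids",
         call. = FALSE)
  unknown <- setdiff(vars, p$covariate_names)
  if (length(unknown))
    stop(sprintf("unknown covariate(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  W <- weights_matrix(w)[match(p$region_ids, w$ids),
                         match(p$region_ids, w$ids), drop = FALSE]
  n <- p$n_regions
  for (v in vars) {
    xm <- matrix(p$X[, v], nrow = n)            # N x T, period-major
    lag <- as.matrix(W %*% xm)
    p$X <- cbind(p$X, as.numeric(lag))
    colnames(p$X)[ncol(p$X)] <- paste0("W*", v)
  }
  p$covariate_names <- colnames(p$X)
  p
}

#' Within (de-trending) transformation
#'
#' Subtracts each region's time mean from the outcome and every covariate,
#' eliminating the constant and the region fixed effects.  The region means
#' are stored in `$means` so that the constant `alpha` and the effects `mu`
#' can be recovered after estimation.  Applying the transformation twice is a
#' no-op (the stored means of the original data are kept).
#'
#' @param p a `panel_data` object with at least 2 periods.
#' @return The transformed panel, `$within = TRUE`.
#' @export
within_transform <- function(p) {
  stopifnot(inherits(p, "panel_data"))
  if (p$n_periods < 2L)
    stop("the within transformation needs at least 2 periods", call. = FALSE)
  if (p$within) return(p)
  n <- p$n_regions
  ybar <- rowMeans(matrix(p$y, nrow = n))
  Xbar <- vapply(seq_len(ncol(p$X)),
                 function(k) rowMeans(matrix(p$X[, k], nrow = n)),
                 numeric(n))
  colnames(Xbar) <- colnames(p$X)
  means <- list(y_region = ybar, X_region = Xbar,
                y_grand = mean(p$y), X_grand = colMeans(p$X))
  p$y <- p$y - ybar[p$region]
  p$X <- p$X - Xbar[p$region, , drop = FALSE]
  p$within <- TRUE
  p$means <- means
  p
}
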