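# Temporal-trend specification: the outcome becomes the first difference
# between consecutive periods while the regressors enter at their
# initial-period values, so the model reads the effect of initial conditions
# on the subsequent change.

#' First-difference panel with lagged regressors
#'
#' For each region and each period t >= 2 builds one row with outcome
#' `y_t - y_{t-1}` and covariates set to their period t-1 values (columns
#' suffixed `"_t-1"`).  With T input periods the result has T-1 periods and
#' `N (T - 1)` rows; balance is preserved, and the differenced panel can be
#' passed to the same fixed-effects / spatial estimators (T-1 >= 2 needed
#' for fixed effects, i.e. at least three input periods).
#'
#' @param p a `panel_data` object with `T >= 2` (levels, not
#'   within-transformed).
#' @return A `panel_data` object of the differenced panel.
#' @export
build_first_difference <- function(p) {
  stopifnot(inherits(p, "panel_data"))
  if (p$within)
    stop("difference the panel before the within transformation",
         call. = FALSE)
  if (p$n_periods < 2L)
    stop("first differencing needs at least 2 periods", call. = FALSE)
  n <- p$n_regions
  ym <- matrix(p$y, nrow = n)
  dy <- ym[, -1L, drop = FALSE] - ym[, -p$n_periods, drop = FALSE]
  lagged_rows <- as.numeric(vapply(seq_len(p$n_periods - 1L),
                                   function(t) (t - 1L) * n + seq_len(n),
                                   numeric(n)))
  X <- p$X[lagged_rows, , drop = FALSE]
  colnames(X) <- paste0(colnames(p$X), "_t-1")
  labels <- paste(p$period_labels[-1L], p$period_labels[-p$n_periods],
                  sep = "-")
  new_panel_data(
    y = as.numeric(dy),
    X = X,
    region_ids = p$region_ids,
    period_labels = labels,
    outcome_name = paste0("d_", p$outcome_name)
  )
}

#' Sign comparison between level and difference models
#'
#' Tabulates, covariate by covariate, the coefficient signs of a levels fit
#' and a first-difference fit (matched by base name, stripping the `"_t-1"`
#' suffix).  A systematic sign reversal is the signature of convergence
#' dynamics: regions with the worst initial conditions post the largest
#' subsequent improvements.  No numerical claim beyond the signs is made.
#'
#' @param fit_levels a `spanel_fit` on the level panel.
#' @param fit_diff a `spanel_fit` on the differenced panel.
#' @param level significance level used to flag coefficients whose sign is
#'   statistically meaningful (default 0.10).
#' @return A data.frame with one row per shared covariate: the two signs,
#'   whether they are opposite, and whether both coefficients are
#'   significant at `level`.
#' @export
sign_flip_interpretation <- function(fit_levels, fit_diff, level = 0.10) {
  stopifnot(inherits(fit_levels, "spanel_fit"),
            inherits(fit_diff, "spanel_fit"))
  base_diff <- sub("_t-1$", "", names(fit_diff$beta))
  shared <- setdiff(intersect(names(fit_levels$beta), base_diff),
                    "(Intercept)")
  if (!length(shared))
    return(data.frame(variable = character(0), sign_level = integer(0),
                      sign_diff = integer(0), opposite = logical(0),
                      both_significant = logical(0)))
  idx <- match(shared, base_diff)
  bl <- fit_levels$beta[shared]
  bd <- fit_diff$beta[idx]
  data.frame(
    variable = shared,
    sign_level = sign(bl),
    sign_diff = sign(bd),
    opposite = sign(bl) * sign(bd) < 0,
    both_significant =
      fit_levels$p_values[shared] <= level &
      fit_diff$p_values[names(fit_diff$beta)[idx]] <= level,
    row.names = NULL
  )
}
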