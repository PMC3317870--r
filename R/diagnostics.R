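# Spatial-dependence diagnostics on least-squares residuals: the pooled-panel
# Lagrange multiplier battery (lag / error, plain and robust) and a
# Breusch-Pagan residual homoscedasticity check.

#' Lagrange-multiplier battery for spatial dependence
#'
#' Score tests on pooled or fixed-effects least-squares residuals for an
#' omitted spatially lagged outcome (LM-lag) and spatially autocorrelated
#' errors (LM-error), with the robust variants that immunize each statistic
#' against the other alternative.  The cross-sectional statistics are applied
#' with the per-period block operator `I_T (x) W`:
#' `LM_err = [e'(I_T (x) W) e / s2]^2 / C` and
#' `LM_lag = [e'(I_T (x) W) y / s2]^2 / J` with
#' `C = T_eff tr(W'W + WW)` and
#' `J = (W X b)' M (W X b) / s2 + C`, `M` the annihilator of the regression
#' design.  For pooled residuals `T_eff = T`; for within-demeaned residuals
#' the demeaning projection leaves `T - 1` effective periods, so
#' `T_eff = T - 1` (using `T` there would make the tests severely
#' undersized).  All four statistics are chi-square with 1 degree of freedom
#' under the null.
#'
#' @param fr a `spanel_fit` from [pooled_ols()] or [fe_ols()] on the same
#'   panel.
#' @param p the `panel_data` the model was fitted on.
#' @param w the row-standardized `spatial_weights`.
#' @param level significance level for the "spatial model warranted" flag
#'   (both plain tests rejecting), default 0.05.
#' @return An `lm_battery` list with elements `lm_lag`, `lm_lag_robust`,
#'   `lm_error`, `lm_error_robust` (each `statistic` + `p_value`), and the
#'   logical `spatial_model_warranted`.
#' @export
lm_tests <- function(fr, p, w, level = 0.05) {
  stopifnot(inherits(fr, "spanel_fit"), inherits(p, "panel_data"),
            inherits(w, "spatial_weights"))
  if (!fr$model_tag %in% c("pooled", "fe"))
    stop("LM tests are defined for pooled or fixed-effects least-squares fits",
         call. = FALSE)
  if (!w$standardized)
    stop("LM tests require row-standardized weights", call. = FALSE)
  if (!setequal(w$ids, p$region_ids) || w$n != fr$n_regions)
    stop("weight matrix does not match the panel", call. = FALSE)
  n <- p$n_regions
  t_eff <- if (fr$model_tag == "fe") fr$n_periods - 1L else fr$n_periods
  perm <- match(p$region_ids, w$ids)
  W <- weights_matrix(w)[perm, perm, drop = FALSE]

  e <- fr$y_used - as.numeric(fr$X_used %*% fr$beta[colnames(fr$X_used)])
  y <- fr$y_used
  X <- fr$X_used
  s2 <- sum(e^2) / (n * t_eff)
  if (s2 <= 0) stop("residual variance is not positive", call. = FALSE)

  tw <- sum(W@x^2) + sum(W * Matrix::t(W))       # tr(W'W) + tr(WW)
  C <- t_eff * tw
  We <- block_lag(W, e, n)
  Wy <- block_lag(W, y, n)
  Wxb <- block_lag(W, as.numeric(X %*% fr$beta[colnames(X)]), n)
  qx <- qr(X)
  mwxb <- qr.resid(qx, Wxb)

  d_err <- sum(e * We) / s2
  d_lag <- sum(e * Wy) / s2
  J <- sum(Wxb * mwxb) / s2 + C

  lm_error <- d_err^2 / C
  lm_lag <- d_lag^2 / J
  lm_lag_robust <- (d_lag - d_err)^2 / (J - C)
  lm_error_robust <- (d_err - (C / J) * d_lag)^2 / (C * (1 - C / J))

  one <- function(s) list(statistic = s,
                          p_value = stats::pchisq(s, df = 1,
                                                  lower.tail = FALSE))
  out <- list(
    lm_lag = one(lm_lag),
    lm_lag_robust = one(lm_lag_robust),
    lm_error = one(lm_error),
    lm_error_robust = one(lm_error_robust),
    model_tag = fr$model_tag,
    level = level
  )
  out$spatial_model_warranted <-
    out$lm_lag$p_value < level && out$lm_error$p_value < level
  class(out) <- "lm_battery"
  out
}

#' @export
#' @method print lm_battery
print.lm_battery <- function(x, ...) {
  cat(sprintf("LM spatial-dependence tests (%s residuals)\n",
              if (x$model_tag == "fe") "fixed-effects" else "pooled"))
  for (nm in c("lm_lag", "lm_lag_robust", "lm_error", "lm_error_robust")) {
    s <- x[[nm]]
    cat(sprintf("  %-16s %10.3f  p = %.4g %s\n", nm, s$statistic,
                s$p_value, significance_stars(s$p_value)))
  }
  cat(sprintf("  spatial model warranted (both plain tests, %.0f%%): %s\n",
              100 * x$level, x$spatial_model_warranted))
  invisible(x)
}

#' Breusch-Pagan homoscedasticity check
#'
#' Koenker's studentized Breusch-Pagan test: the squared residuals are
#' regressed on the model covariates and `n R^2` of that auxiliary
#' regression is referred to a chi-square with K degrees of freedom.
#' Constant residuals are degenerate and return statistic 0, p = 1.
#'
#' @param fr a `spanel_fit` with residuals on the estimation scale.
#' @param p the `panel_data` the model was fitted on (unused beyond
#'   consistency checks; the design is taken from the fit).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
homoscedasticity_check <- function(fr, p) {
  stopifnot(inherits(fr, "spanel_fit"))
  e <- fr$y_used - as.numeric(fr$X_used %*% fr$beta[colnames(fr$X_used)])
  if (fr$model_tag == "fe_sar")
    e <- e - fr$spatial_param[["delta"]] * fr$Wy_used
  if (fr$model_tag == "fe_sea")
    e <- fr$residuals_filtered          # whitened residuals under the model
  X <- fr$X_used[, setdiff(colnames(fr$X_used), "(Intercept)"), drop = FALSE]
  e2 <- e^2
  if (stats::sd(e2) < 1e-14 * max(mean(e2), 1))
    return(list(statistic = 0, df = ncol(X), p_value = 1))
  aux <- qr_ols(cbind(`(Intercept)` = 1, X), e2)
  r2 <- 1 - sum(aux$resid^2) / sum((e2 - mean(e2))^2)
  stat <- length(e) * r2
  list(statistic = stat, df = ncol(X),
       p_value = stats::pchisq(stat, df = ncol(X), lower.tail = FALSE))
}
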