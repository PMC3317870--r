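# Least-squares estimators: pooled OLS and the fixed-effects (within)
# estimator.  Both return a `spanel_fit`, the common result container also
# used by the spatial ML estimators.

qr_ols <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- colnames(X)[qx$pivot[seq_len(qx$rank)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(setdiff(colnames(X), keep), collapse = ", ")),
         call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  list(qr = qx, beta = beta, fitted = as.numeric(X %*% beta),
       resid = y - as.numeric(X %*% beta))
}

new_spanel_fit <- function(model_tag, beta, alpha, mu, spatial_param, sigma2,
                           se, loglik, loglik_nc, r2, corr2, aic, residuals,
                           fitted, n_obs, n_regions, n_periods, df_resid,
                           y_used, X_used, extra = list()) {
  est <- c(beta, spatial_param)
  z <- est / se[names(est)]
  out <- list(
    model_tag = model_tag,
    beta = beta,
    alpha = alpha,
    mu = mu,
    spatial_param = spatial_param,
    sigma2 = sigma2,
    std_errors = se,
    z_stats = z,
    p_values = 2 * stats::pnorm(-abs(z)),
    loglik = loglik,
    loglik_no_constant = loglik_nc,
    r2 = r2,
    corr2 = corr2,
    aic = aic,
    residuals = residuals,
    fitted = fitted,
    n_obs = n_obs,
    n_regions = n_regions,
    n_periods = n_periods,
    df_resid = df_resid,
    y_used = y_used,
    X_used = X_used
  )
  out[names(extra)] <- extra
  class(out) <- "spanel_fit"
  out
}

#' Significance stars for p-values
#'
#' `***`, `**`, `*` at the 1, 5 and 10 per cent levels, thresholds inclusive
#' (a p-value of exactly 0.05 maps to `**`).
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "***",
         ifelse(p <= 0.05, "**",
                ifelse(p <= 0.10, "*", "")))
}

#' @export
#' @method print spanel_fit
print.spanel_fit <- function(x, ...) {
  tag <- c(pooled = "Pooled OLS", fe = "Fixed effects (within)",
           fe_sea = "Fixed effects spatial error (ML)",
           fe_sar = "Fixed effects spatial lag (ML)")[x$model_tag]
  cat(tag, "\n")
  nm <- names(x$beta)
  tab <- data.frame(
    Estimate = round(x$beta, 4),
    Std.Error = round(x$std_errors[nm], 4),
    z = round(x$z_stats[nm], 2),
    `Pr(>|z|)` = signif(x$p_values[nm], 3),
    ` ` = significance_stars(x$p_values[nm]),
    check.names = FALSE
  )
  print(tab)
  if (!is.null(x$spatial_param)) {
    sp <- names(x$spatial_param)
    cat(sprintf("%s = %.4f (se %.4f) %s\n", sp, x$spatial_param,
                x$std_errors[sp], significance_stars(x$p_values[sp])))
  }
  cat(sprintf("sigma2 = %.4f  R2 = %.4f  corr2 = %.4f\n",
              x$sigma2, x$r2, x$corr2))
  cat(sprintf("loglik = %.2f  AIC = %.2f  N = %d\n",
              x$loglik, x$aic, x$n_obs))
  invisible(x)
}

#' @export
coef.spanel_fit <- function(object, ...) object$beta

#' @export
logLik.spanel_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) +
              length(object$spatial_param) + 1, class = "logLik")
}

#' @export
residuals.spanel_fit <- function(object, ...) object$residuals

#' @export
fitted.spanel_fit <- function(object, ...) object$fitted

#' Pooled ordinary least squares
#'
#' The pooled model `y = alpha + X beta + eps`, ignoring regional
#' heterogeneity, with classical standard errors and
#' `sigma2 = e'e / (NT - K - 1)`.
#'
#' @param p a `panel_data` object (not within-transformed).
#' @return A `spanel_fit` with `model_tag = "pooled"`.
#' @export
pooled_ols <- function(p) {
  stopifnot(inherits(p, "panel_data"))
  if (p$within)
    stop("`pooled_ols()` expects the untransformed panel", call. = FALSE)
  nt <- length(p$y)
  K <- ncol(p$X)
  if (nt <= K + 1L)
    stop("too few observations for the pooled model", call. = FALSE)
  X1 <- cbind(`(Intercept)` = 1, p$X)
  fit <- qr_ols(X1, p$y)
  sse <- sum(fit$resid^2)
  sigma2 <- sse / (nt - K - 1L)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X1)[fit$qr$pivot]
  se <- se[colnames(X1)]
  sst <- sum((p$y - mean(p$y))^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (nt - 1) / (nt - K - 1)
  ll <- -nt / 2 * (log(2 * pi) + 1 + log(sse / nt))
  ll_nc <- -nt / 2 * (1 + log(sse / nt))
  new_spanel_fit(
    model_tag = "pooled",
    beta = fit$beta,
    alpha = unname(fit$beta["(Intercept)"]),
    mu = NULL,
    spatial_param = NULL,
    sigma2 = sigma2,
    se = se,
    loglik = ll, loglik_nc = ll_nc,
    r2 = r2,
    corr2 = stats::cor(p$y, fit$fitted)^2,
    aic = -2 * ll + 2 * (K + 2),
    residuals = fit$resid,
    fitted = fit$fitted,
    n_obs = nt, n_regions = p$n_regions, n_periods = p$n_periods,
    df_resid = nt - K - 1L,
    y_used = p$y, X_used = X1,
    extra = list(adj_r2 = adj_r2)
  )
}

#' Fixed-effects (within) estimator
#'
#' Demeans outcome and covariates by region, estimates `beta` by least
#' squares on the transformed data, and recovers the grand constant and the
#' region effects under the normalization `sum(mu) = 0`.  Identical to least
#' squares with one dummy per region (LSDV).  `sigma2 = e'e / (NT - N - K)`.
#'
#' @param p a `panel_data` object with `T >= 2`.
#' @return A `spanel_fit` with `model_tag = "fe"`, including `alpha` and the
#'   vector `mu` of recovered fixed effects.
#' @export
fe_ols <- function(p) {
  stopifnot(inherits(p, "panel_data"))
  wp <- within_transform(p)
  check_within_variation(wp)
  nt <- length(wp$y)
  n <- p$n_regions; K <- ncol(wp$X)
  fit <- qr_ols(wp$X, wp$y)
  sse <- sum(fit$resid^2)
  df <- nt - n - K
  if (df <= 0L)
    stop("no residual degrees of freedom in the fixed-effects model",
         call. = FALSE)
  sigma2 <- sse / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(wp$X)[fit$qr$pivot]
  se <- se[colnames(wp$X)]
  alpha <- wp$means$y_grand - sum(wp$means$X_grand * fit$beta)
  mu <- as.numeric(wp$means$y_region - wp$means$X_region %*% fit$beta - alpha)
  names(mu) <- p$region_ids
  fitted_orig <- alpha + unname(mu[p$region]) +
    as.numeric((if (p$within) p$X + wp$means$X_region[p$region, , drop = FALSE]
                else p$X) %*% fit$beta)
  y_orig <- if (p$within) p$y + wp$means$y_region[p$region] else p$y
  ll <- -nt / 2 * (log(2 * pi) + 1 + log(sse / nt))
  ll_nc <- -nt / 2 * (1 + log(sse / nt))
  new_spanel_fit(
    model_tag = "fe",
    beta = fit$beta,
    alpha = alpha,
    mu = mu,
    spatial_param = NULL,
    sigma2 = sigma2,
    se = se,
    loglik = ll, loglik_nc = ll_nc,
    r2 = 1 - sse / sum(wp$y^2),
    corr2 = stats::cor(y_orig, fitted_orig)^2,
    aic = -2 * ll + 2 * (K + 1),
    residuals = unname(y_orig - fitted_orig),
    fitted = fitted_orig,
    n_obs = nt, n_regions = n, n_periods = p$n_periods,
    df_resid = df,
    y_used = wp$y, X_used = wp$X
  )
}

check_within_variation <- function(wp) {
  scale <- pmax(colMeans(abs(wp$X)), 1)
  dead <- colnames(wp$X)[apply(wp$X, 2, stats::sd) < 1e-10 * scale]
  if (length(dead))
    stop(sprintf(
      "covariate(s) without within-region variation (absorbed by the fixed effects): %s",
      paste(dead, collapse = ", ")), call. = FALSE)
  invisible(wp)
}
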