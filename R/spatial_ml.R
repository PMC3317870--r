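# Maximum-likelihood estimation of the fixed-effects spatial-error (SEA) and
# spatial-lag (SAR) panel models on within-transformed data.  Both estimators
# concentrate the likelihood to a scalar function of the spatial parameter;
# the log-determinant ln|I - rho W| enters through the cached eigenvalues of
# the row-standardized weight matrix.

#' Settings for the spatial ML estimators
#'
#' @param param_bounds open interval for the spatial parameter; default
#'   `(1/min(lambda) + 1e-6, 1 - 1e-6)` from the spectrum of W, the region
#'   where `I - rho W` stays invertible.
#' @param tol convergence tolerance on the spatial parameter for the
#'   iterative two-stage spatial-error loop (default `1e-8`).
#' @param max_iter iteration cap for that loop (default 100).
#' @param se_method `"information_matrix"` (analytic, default) or
#'   `"numerical_hessian"` (curvature of the concentrated likelihood, avoids
#'   the dense `W (I - rho W)^-1` needed for the analytic trace terms).
#' @param df_adjust logical; when `TRUE` (default) variances are computed on
#'   the effective sample `N (T - 1)` of the demeaned data rather than `NT`.
#'   The reported `sigma2` always follows the `e'e / NT` convention.
#' @return A `spatial_ml_settings` list.
#' @export
spatial_ml_settings <- function(param_bounds = NULL, tol = 1e-8,
                                max_iter = 100L,
                                se_method = c("information_matrix",
                                              "numerical_hessian"),
                                df_adjust = TRUE) {
  stopifnot(tol > 0, max_iter >= 1L)
  structure(
    list(param_bounds = param_bounds, tol = tol,
         max_iter = as.integer(max_iter),
         se_method = match.arg(se_method),
         df_adjust = isTRUE(df_adjust)),
    class = "spatial_ml_settings"
  )
}

#' Log-Jacobian of the spatial filter
#'
#' `T * sum_i ln(1 - rho * lambda_i) = T * ln|I_N - rho W|`, the eigenvalue
#' ("algebraic") form of the log-determinant appearing in the concentrated
#' log-likelihoods, valid while `1 - rho * lambda_i > 0` for every i.
#'
#' @param rho scalar spatial parameter.
#' @param spectrum eigenvalues of the row-standardized W
#'   (see [eigenvalues()]).
#' @param n_periods number of panel periods T.
#' @return Scalar log-Jacobian.
#' @export
log_jacobian <- function(rho, spectrum, n_periods) {
  v <- 1 - rho * spectrum
  if (any(v <= 0))
    stop(sprintf("rho = %g is outside the invertibility region of I - rho W",
                 rho), call. = FALSE)
  n_periods * sum(log(v))
}

# Per-period application of W to a period-major stacked vector.
block_lag <- function(W, v, n) {
  as.numeric(as.matrix(W %*% matrix(v, nrow = n)))
}

prep_fe_spatial <- function(p, w) {
  stopifnot(inherits(p, "panel_data"), inherits(w, "spatial_weights"))
  if (!w$standardized)
    stop("spatial ML estimation requires row-standardized weights",
         call. = FALSE)
  if (!setequal(w$ids, p$region_ids))
    stop("weight matrix ids do not match the panel's region ids",
         call. = FALSE)
  if (p$n_periods < 2L)
    stop("fixed-effects spatial models need at least 2 periods",
         call. = FALSE)
  perm <- match(p$region_ids, w$ids)
  W <- weights_matrix(w)[perm, perm, drop = FALSE]
  ev <- eigenvalues(w)
  wp <- within_transform(p)
  check_within_variation(wp)
  list(wp = wp, W = W, ev = ev,
       n = p$n_regions, t = p$n_periods, nt = length(p$y))
}

default_bounds <- function(settings, ev) {
  b <- settings$param_bounds
  if (is.null(b)) b <- c(1 / min(ev) + 1e-6, 1 - 1e-6)
  if (b[1] >= b[2] || any(1 - b * max(ev) <= 0) || any(1 - b * min(ev) <= 0))
    stop("`param_bounds` must lie strictly inside the invertibility region",
         call. = FALSE)
  b
}

#' Fixed-effects spatial-error model by maximum likelihood
#'
#' The spatial-error specification lets the disturbance follow a spatial
#' autoregression `phi_t = rho W phi_t + eps_t` on top of the fixed-effects
#' mean model.  After demeaning, estimation alternates two stages until the
#' spatial autocorrelation coefficient converges: given rho, the spatially
#' filtered regression of `(I - rho W) y*` on `(I - rho W) X*` yields beta;
#' given beta, the concentrated log-likelihood
#' `L(rho) = -(NT/2) ln(e(rho)'e(rho)/NT) + T sum ln(1 - rho lambda_i)`
#' with `e(rho) = (I - rho W)(y* - X* beta)` is maximized by bounded scalar
#' optimization.  The constant and region effects are recovered from the
#' stored region means.
#'
#' @param p a `panel_data` object (levels; demeaning is internal).
#' @param w a row-standardized `spatial_weights` object.
#' @param settings a [spatial_ml_settings()] list.
#' @param rho optional fixed value; skips estimation of the spatial
#'   parameter (with `rho = 0` the fit reproduces [fe_ols()] coefficients).
#' @return A `spanel_fit` with `model_tag = "fe_sea"` and
#'   `spatial_param = c(rho = ...)`.
#' @export
fit_fe_sea <- function(p, w, settings = spatial_ml_settings(), rho = NULL) {
  pr <- prep_fe_spatial(p, w)
  wp <- pr$wp; W <- pr$W; ev <- pr$ev
  n <- pr$n; t <- pr$t; nt <- pr$nt
  ystar <- wp$y; Xstar <- wp$X
  Wy <- block_lag(W, ystar, n)
  WX <- apply(Xstar, 2, block_lag, W = W, n = n)
  bounds <- default_bounds(settings, ev)

  stage1 <- function(r) qr_ols(Xstar - r * WX, ystar - r * Wy)

  if (is.null(rho)) {
    rho_c <- 0
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(settings$max_iter)) {
      beta <- stage1(rho_c)$beta
      u <- ystar - as.numeric(Xstar %*% beta)
      Wu <- block_lag(W, u, n)
      uu <- sum(u * u); uWu <- sum(u * Wu); WuWu <- sum(Wu * Wu)
      prof <- function(r)
        -nt / 2 * log((uu - 2 * r * uWu + r^2 * WuWu) / nt) +
          t * sum(log(1 - r * ev))
      rho_new <- stats::optimize(prof, lower = bounds[1], upper = bounds[2],
                                 maximum = TRUE, tol = 1e-10)$maximum
      trace <- c(trace, rho_new)
      if (abs(rho_new - rho_c) < settings$tol) {
        rho_c <- rho_new
        converged <- TRUE
        break
      }
      rho_c <- rho_new
    }
    if (!converged)
      stop(errorCondition(
        sprintf("spatial-error two-stage loop did not converge in %d iterations (last iterates: %s)",
                settings$max_iter,
                paste(sprintf("%.6f", utils::tail(trace, 5L)), collapse = ", ")),
        class = c("spanel_convergence_error", "error", "condition"),
        trace = trace))
    if (min(abs(rho_c - bounds)) < 1e-5)
      warning("spatial parameter estimate is pinned at a bound",
              call. = FALSE)
    rho_hat <- rho_c
    n_iter <- it
  } else {
    if (any(1 - rho * ev <= 0))
      stop("fixed `rho` is outside the invertibility region", call. = FALSE)
    rho_hat <- rho
    trace <- rho
    n_iter <- 0L
  }

  fin <- stage1(rho_hat)
  beta <- fin$beta
  e <- fin$resid
  sse <- sum(e^2)
  sigma2 <- sse / nt
  t_eff <- if (settings$df_adjust) t - 1L else t
  n_eff <- n * t_eff
  s2t <- sse / n_eff

  XtXinv <- chol2inv(qr.R(fin$qr))
  se_beta <- sqrt(diag(XtXinv) * s2t)
  names(se_beta) <- colnames(Xstar)[fin$qr$pivot]
  se_beta <- se_beta[colnames(Xstar)]

  g <- ev / (1 - rho_hat * ev)
  tr_g <- sum(g); tr_g2 <- sum(g^2)
  se_rho <- if (settings$se_method == "information_matrix") {
    Bd <- diag(n) - rho_hat * as.matrix(W)
    G <- as.matrix(W) %*% solve(Bd)
    tr_gtg <- sum(G * G)
    i_rr <- t_eff * (tr_g2 + tr_gtg)
    i_rs <- t_eff * tr_g / s2t
    i_ss <- n_eff / (2 * s2t^2)
    sqrt(1 / (i_rr - i_rs^2 / i_ss))
  } else {
    prof_full <- function(r) {
      s <- sum(qr_ols(Xstar - r * WX, ystar - r * Wy)$resid^2)
      -nt / 2 * log(s / nt) + t * sum(log(1 - r * ev))
    }
    h <- 1e-5
    lpp <- (prof_full(rho_hat + h) - 2 * prof_full(rho_hat) +
              prof_full(rho_hat - h)) / h^2
    sqrt(-1 / (t_eff / t * lpp))
  }

  ll <- -nt / 2 * (log(2 * pi) + 1 + log(sigma2)) + t * sum(log(1 - rho_hat * ev))
  ll_nc <- ll + nt / 2 * log(2 * pi)

  alpha <- wp$means$y_grand - sum(wp$means$X_grand * beta)
  mu <- as.numeric(wp$means$y_region - wp$means$X_region %*% beta - alpha)
  names(mu) <- p$region_ids
  X_orig <- if (p$within) p$X + wp$means$X_region[p$region, , drop = FALSE] else p$X
  y_orig <- if (p$within) p$y + wp$means$y_region[p$region] else p$y
  fitted_orig <- alpha + unname(mu[p$region]) + as.numeric(X_orig %*% beta)
  u_hat <- ystar - as.numeric(Xstar %*% beta)
  K <- ncol(Xstar)

  new_spanel_fit(
    model_tag = "fe_sea",
    beta = beta,
    alpha = alpha,
    mu = mu,
    spatial_param = c(rho = rho_hat),
    sigma2 = sigma2,
    se = c(se_beta, rho = se_rho),
    loglik = ll, loglik_nc = ll_nc,
    r2 = 1 - sum(u_hat^2) / sum(ystar^2),
    corr2 = stats::cor(y_orig, fitted_orig)^2,
    aic = -2 * ll + 2 * (K + 2),
    residuals = unname(y_orig - fitted_orig),
    fitted = fitted_orig,
    n_obs = nt, n_regions = n, n_periods = t,
    df_resid = nt - n - K - 1L,
    y_used = ystar, X_used = Xstar,
    extra = list(settings = settings, iterations = n_iter,
                 rho_trace = trace, sigma2_df = s2t,
                 residuals_filtered = e)
  )
}

#' Fixed-effects spatial-lag model by maximum likelihood
#'
#' The spatial-lag (autoregressive) specification includes the neighbour
#' average of the outcome as a regressor:
#' `y_t = delta W y_t + X_t beta + mu + eps_t`.  On the demeaned data the
#' likelihood concentrates to a scalar function of delta through the two
#' auxiliary regressions of `y*` and `W y*` on `X*`:
#' `L(delta) = -(NT/2) ln(e(delta)'e(delta)/NT) + T sum ln(1 - delta lambda_i)`
#' with `e(delta) = e_0 - delta e_d`.  A single bounded scalar optimization
#' yields delta, after which `beta(delta) = b_0 - delta b_d`.
#'
#' @inheritParams fit_fe_sea
#' @param delta optional fixed value of the spatial autoregressive
#'   coefficient.
#' @return A `spanel_fit` with `model_tag = "fe_sar"` and
#'   `spatial_param = c(delta = ...)`.
#' @export
fit_fe_sar <- function(p, w, settings = spatial_ml_settings(), delta = NULL) {
  pr <- prep_fe_spatial(p, w)
  wp <- pr$wp; W <- pr$W; ev <- pr$ev
  n <- pr$n; t <- pr$t; nt <- pr$nt
  ystar <- wp$y; Xstar <- wp$X
  Wy <- block_lag(W, ystar, n)
  bounds <- default_bounds(settings, ev)

  qx <- qr(Xstar)
  if (qx$rank < ncol(Xstar))
    stop("design matrix is rank deficient after demeaning", call. = FALSE)
  b0 <- qr.coef(qx, ystar); e0 <- qr.resid(qx, ystar)
  bd <- qr.coef(qx, Wy);    ed <- qr.resid(qx, Wy)
  e00 <- sum(e0 * e0); e0d <- sum(e0 * ed); edd <- sum(ed * ed)
  prof <- function(d)
    -nt / 2 * log((e00 - 2 * d * e0d + d^2 * edd) / nt) +
      t * sum(log(1 - d * ev))

  if (is.null(delta)) {
    delta_hat <- stats::optimize(prof, lower = bounds[1], upper = bounds[2],
                                 maximum = TRUE, tol = 1e-10)$maximum
    if (min(abs(delta_hat - bounds)) < 1e-5)
      warning("spatial parameter estimate is pinned at a bound",
              call. = FALSE)
  } else {
    if (any(1 - delta * ev <= 0))
      stop("fixed `delta` is outside the invertibility region", call. = FALSE)
    delta_hat <- delta
  }

  beta <- b0 - delta_hat * bd
  e <- e0 - delta_hat * ed
  sse <- sum(e^2)
  sigma2 <- sse / nt
  t_eff <- if (settings$df_adjust) t - 1L else t
  n_eff <- n * t_eff
  s2t <- sse / n_eff
  K <- ncol(Xstar)

  g <- ev / (1 - delta_hat * ev)
  tr_g <- sum(g); tr_g2 <- sum(g^2)
  if (settings$se_method == "information_matrix") {
    Ad <- diag(n) - delta_hat * as.matrix(W)
    G <- as.matrix(W) %*% solve(Ad)
    tr_gtg <- sum(G * G)
    xb <- matrix(as.numeric(Xstar %*% beta), nrow = n)
    pv <- as.numeric(G %*% xb)               # (I_T (x) G) X* beta, stacked
    info <- matrix(0, K + 2L, K + 2L)
    info[seq_len(K), seq_len(K)] <- crossprod(Xstar) / s2t
    info[seq_len(K), K + 1L] <- crossprod(Xstar, pv) / s2t
    info[K + 1L, seq_len(K)] <- info[seq_len(K), K + 1L]
    info[K + 1L, K + 1L] <- t_eff * (tr_g2 + tr_gtg) + sum(pv^2) / s2t
    info[K + 1L, K + 2L] <- info[K + 2L, K + 1L] <- t_eff * tr_g / s2t
    info[K + 2L, K + 2L] <- n_eff / (2 * s2t^2)
    vc <- solve(info)
    se_beta <- sqrt(diag(vc)[seq_len(K)])
    names(se_beta) <- colnames(Xstar)
    se_delta <- sqrt(vc[K + 1L, K + 1L])
  } else {
    XtXinv <- chol2inv(qr.R(qx))
    se_beta <- sqrt(diag(XtXinv) * s2t)
    names(se_beta) <- colnames(Xstar)[qx$pivot]
    se_beta <- se_beta[colnames(Xstar)]
    h <- 1e-5
    lpp <- (prof(delta_hat + h) - 2 * prof(delta_hat) +
              prof(delta_hat - h)) / h^2
    se_delta <- sqrt(-1 / (t_eff / t * lpp))
  }

  ll <- -nt / 2 * (log(2 * pi) + 1 + log(sigma2)) +
    t * sum(log(1 - delta_hat * ev))
  ll_nc <- ll + nt / 2 * log(2 * pi)

  X_orig <- if (p$within) p$X + wp$means$X_region[p$region, , drop = FALSE] else p$X
  y_orig <- if (p$within) p$y + wp$means$y_region[p$region] else p$y
  Wy_raw <- block_lag(W, y_orig, n)
  wybar <- rowMeans(matrix(Wy_raw, nrow = n))
  alpha <- mean(y_orig) - delta_hat * mean(Wy_raw) -
    sum(wp$means$X_grand * beta)
  mu <- as.numeric(wp$means$y_region - delta_hat * wybar -
                     wp$means$X_region %*% beta - alpha)
  names(mu) <- p$region_ids
  fitted_orig <- alpha + unname(mu[p$region]) + delta_hat * Wy_raw +
    as.numeric(X_orig %*% beta)

  new_spanel_fit(
    model_tag = "fe_sar",
    beta = beta,
    alpha = alpha,
    mu = mu,
    spatial_param = c(delta = delta_hat),
    sigma2 = sigma2,
    se = c(se_beta, delta = se_delta),
    loglik = ll, loglik_nc = ll_nc,
    r2 = 1 - sse / sum(ystar^2),
    corr2 = stats::cor(y_orig, fitted_orig)^2,
    aic = -2 * ll + 2 * (K + 2),
    residuals = unname(y_orig - fitted_orig),
    fitted = fitted_orig,
    n_obs = nt, n_regions = n, n_periods = t,
    df_resid = nt - n - K - 1L,
    y_used = ystar, X_used = Xstar,
    extra = list(settings = settings, sigma2_df = s2t,
                 Wy_used = Wy)
  )
}

#' Recompute goodness-of-fit statistics for a fit
#'
#' `r2` is computed on the estimation scale (within scale for the
#' fixed-effects family), `corr2` as the squared Pearson correlation of
#' observed and fitted outcomes on the original (pre-demeaning) scale, and
#' `aic = -2 loglik + 2k` with `k = K + #spatial parameters + 1` (the fixed
#' effects are concentrated out and not counted).
#'
#' @param fr a `spanel_fit`.
#' @return The fit with `r2`, `corr2` and `aic` recomputed.
#' @export
fit_statistics <- function(fr) {
  stopifnot(inherits(fr, "spanel_fit"))
  y_obs <- fr$fitted + fr$residuals
  if (stats::var(y_obs) == 0)
    stop("observed outcome has zero variance", call. = FALSE)
  eta <- as.numeric(fr$X_used %*% fr$beta[colnames(fr$X_used)])
  if (fr$model_tag == "fe_sar")
    eta <- eta + fr$spatial_param[["delta"]] * fr$Wy_used
  res_est <- fr$y_used - eta
  sst <- if (fr$model_tag == "pooled")
    sum((fr$y_used - mean(fr$y_used))^2) else sum(fr$y_used^2)
  fr$r2 <- 1 - sum(res_est^2) / sst
  fr$corr2 <- stats::cor(y_obs, fr$fitted)^2
  k <- length(fr$beta) + length(fr$spatial_param) + 1L
  fr$aic <- -2 * fr$loglik + 2 * k
  fr
}
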