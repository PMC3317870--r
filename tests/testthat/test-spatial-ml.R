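test_that("log-Jacobian matches closed forms and the dense determinant", {
  w12 <- row_standardize(build_lattice_weights(1, 2))
  ev <- eigenvalues(w12)
  expect_equal(log_jacobian(0, ev, 3), 0)
  expect_equal(log_jacobian(0.5, ev, 1), log(0.75), tolerance = 1e-12)

  w <- row_standardize(build_lattice_weights(7, 7))
  ev <- eigenvalues(w)
  Wd <- as.matrix(weights_matrix(w))
  for (rho in c(-0.6, 0.3, 0.786)) {
    dense <- determinant(diag(49) - rho * Wd, logarithm = TRUE)
    expect_equal(log_jacobian(rho, ev, 3), 3 * as.numeric(dense$modulus),
                 tolerance = 1e-9)
  }
  expect_error(log_jacobian(1.5, ev, 3), "invertibility")
})

test_that("spatial-error ML at rho = 0 reproduces the within estimator", {
  cfg <- synthetic_config(rows = 7, cols = 7, seed = 31)
  sim <- simulate_panel(cfg)
  fe <- fe_ols(sim$panel)
  sea0 <- fit_fe_sea(sim$panel, sim$weights, rho = 0)
  expect_equal(sea0$beta, fe$beta, tolerance = 1e-8)
  expect_equal(sea0$loglik, fe$loglik, tolerance = 1e-8)
})

test_that("concentrated-likelihood maximizers match a fine grid search", {
  cfg <- synthetic_config(rows = 7, cols = 7, seed = 33)
  sim <- simulate_panel(cfg)
  p <- sim$panel; w <- sim$weights
  wp <- within_transform(p)
  ev <- eigenvalues(w)
  W <- weights_matrix(w)
  n <- p$n_regions; t <- p$n_periods; nt <- length(p$y)
  blk <- function(v) as.numeric(as.matrix(W %*% matrix(v, n)))
  Wy <- blk(wp$y)
  WX <- apply(wp$X, 2, blk)
  grid <- seq(1 / min(ev) + 1e-3, 1 - 1e-3, by = 1e-4)

  # SEA: profile beta out at every grid point by filtered least squares
  prof_sea <- vapply(grid, function(r) {
    e <- stats::lm.fit(wp$X - r * WX, wp$y - r * Wy)$residuals
    -nt / 2 * log(sum(e^2) / nt) + t * sum(log(1 - r * ev))
  }, numeric(1))
  sea <- fit_fe_sea(p, w)
  expect_lt(abs(sea$spatial_param[["rho"]] - grid[which.max(prof_sea)]),
            1e-4 + 1e-9)
  expect_gte(max(prof_sea[abs(grid - sea$spatial_param) < 2e-4]),
             max(prof_sea) - 1e-6)

  # SAR: profile beta out of the filtered outcome regression
  cfg2 <- synthetic_config(rows = 7, cols = 7, process = "sar", seed = 34)
  sim2 <- simulate_panel(cfg2, w)
  sar <- fit_fe_sar(sim2$panel, w)
  wp2 <- within_transform(sim2$panel)
  Wy2 <- blk(wp2$y)
  prof_sar <- vapply(grid, function(d) {
    e <- stats::lm.fit(wp2$X, wp2$y - d * Wy2)$residuals
    -nt / 2 * log(sum(e^2) / nt) + t * sum(log(1 - d * ev))
  }, numeric(1))
  expect_lt(abs(sar$spatial_param[["delta"]] - grid[which.max(prof_sar)]),
            1e-4 + 1e-9)
})

test_that("spatial likelihoods nest the fixed-effects model", {
  for (seed in c(41, 42)) {
    for (proc in c("sea", "sar", "none")) {
      cfg <- synthetic_config(rows = 7, cols = 7, process = proc, seed = seed)
      sim <- simulate_panel(cfg)
      fe <- fe_ols(sim$panel)
      sea <- fit_fe_sea(sim$panel, sim$weights)
      sar <- fit_fe_sar(sim$panel, sim$weights)
      expect_gte(sea$loglik, fe$loglik - 1e-8)
      expect_gte(sar$loglik, fe$loglik - 1e-8)
    }
  }
})

test_that("a spatially independent DGP yields a near-zero spatial parameter", {
  cfg <- synthetic_config(process = "none", seed = 51)
  sim <- simulate_panel(cfg)
  sea <- fit_fe_sea(sim$panel, sim$weights)
  expect_lt(abs(sea$spatial_param[["rho"]]), 4 * sea$std_errors["rho"])
  fe <- fe_ols(sim$panel)
  expect_lt(max(abs(sea$beta - fe$beta) / fe$std_errors[names(fe$beta)]), 0.5)
  sar <- fit_fe_sar(sim$panel, sim$weights)
  expect_lt(abs(sar$spatial_param[["delta"]]), 4 * sar$std_errors["delta"])
})

test_that("the two-stage loop reports non-convergence with its iterate trace", {
  cfg <- synthetic_config(rows = 7, cols = 7, seed = 52)
  sim <- simulate_panel(cfg)
  err <- tryCatch(
    fit_fe_sea(sim$panel, sim$weights,
               spatial_ml_settings(tol = 1e-14, max_iter = 1L)),
    error = function(e) e)
  expect_s3_class(err, "spanel_convergence_error")
  expect_true(length(err$trace) >= 1)
})

test_that("numerical-Hessian standard errors agree with the information matrix", {
  cfg <- synthetic_config(rows = 10, cols = 10, seed = 53)
  sim <- simulate_panel(cfg)
  a <- fit_fe_sea(sim$panel, sim$weights,
                  spatial_ml_settings(se_method = "information_matrix"))
  b <- fit_fe_sea(sim$panel, sim$weights,
                  spatial_ml_settings(se_method = "numerical_hessian"))
  expect_equal(unname(a$std_errors["rho"]), unname(b$std_errors["rho"]),
               tolerance = 0.05)
})

test_that("fit statistics: perfect fit, AIC arithmetic, recomputation", {
  df <- make_long_panel(n = 6, t = 3, k = 2, seed = 55)
  p <- validate_panel(df, outcome = "y")
  pe <- p; pe$y <- 1 + as.numeric(p$X %*% c(2, -1))
  f <- pooled_ols(pe)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$corr2, 1, tolerance = 1e-12)

  cfg <- synthetic_config(rows = 5, cols = 5, seed = 56)
  sim <- simulate_panel(cfg)
  sea <- fit_fe_sea(sim$panel, sim$weights)
  sar <- fit_fe_sar(sim$panel, sim$weights)
  k <- length(sea$beta) + 2
  expect_equal(sea$aic, -2 * sea$loglik + 2 * k, tolerance = 1e-10)
  expect_equal(sar$aic, -2 * sar$loglik + 2 * k, tolerance = 1e-10)
  # AIC ordering is pure arithmetic on the log-likelihoods here (equal k)
  expect_equal(sea$aic < sar$aic, sea$loglik > sar$loglik)

  re <- fit_statistics(sea)
  expect_equal(re$r2, sea$r2, tolerance = 1e-10)
  expect_equal(re$corr2, sea$corr2, tolerance = 1e-10)
  expect_equal(re$aic, sea$aic, tolerance = 1e-10)

  # corr2 is invariant to a common shift of observed and fitted
  y_obs <- sea$fitted + sea$residuals
  expect_equal(stats::cor(y_obs + 5, sea$fitted + 5)^2, sea$corr2,
               tolerance = 1e-12)
})

test_that("recovered fixed effects are centred and reconstruct the outcome", {
  cfg <- synthetic_config(rows = 7, cols = 7, sigma_mu = 0.4, seed = 57)
  sim <- simulate_panel(cfg)
  for (f in list(fit_fe_sea(sim$panel, sim$weights),
                 fit_fe_sar(sim$panel, sim$weights))) {
    expect_equal(sum(f$mu), 0, tolerance = 1e-8)
    expect_equal(f$fitted + f$residuals, sim$panel$y, tolerance = 1e-10)
  }
})
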