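test_that("long records validate into a period-major balanced panel", {
  df <- data.frame(
    region_id = c("r2", "r1", "r2", "r1"),
    period = c("t1", "t1", "t2", "t2"),
    y = c(2, 1, 4, 3),
    x1 = c(20, 10, 40, 30)
  )
  p <- validate_panel(df, outcome = "y")
  expect_s3_class(p, "panel_data")
  expect_equal(p$y, c(1, 2, 3, 4))       # (r1,t1),(r2,t1),(r1,t2),(r2,t2)
  expect_equal(unname(p$X[, "x1"]), c(10, 20, 30, 40))

  shuffled <- df[c(3, 1, 4, 2), ]
  expect_equal(validate_panel(shuffled, outcome = "y"), p)

  expect_error(validate_panel(df[-2, ], outcome = "y"),
               "missing \\(region, period\\) pair.*r1, t1")
  expect_error(validate_panel(rbind(df, df[1, ]), outcome = "y"),
               "duplicated")
  df$x1 <- as.character(df$x1)
  expect_error(validate_panel(df, outcome = "y", covariates = "x1"),
               "numeric")
})

test_that("period_order overrides lexicographic period sorting", {
  df <- make_long_panel(n = 3, t = 2)
  p <- validate_panel(df, outcome = "y", period_order = c("t2", "t1"))
  expect_equal(p$period_labels, c("t2", "t1"))
  expect_equal(p$y[1:3], df$y[df$period == "t2"][order(df$region_id[df$period == "t2"])])
})

test_that("outcome log transform is exact, invertible and guarded", {
  df <- make_long_panel(n = 3, t = 2)
  df$y <- abs(df$y) + 0.5
  p <- validate_panel(df, outcome = "y")

  p1 <- p; p1$y[1] <- 1
  expect_equal(log_outcome(p1)$y[1], 0)

  # descriptive tables of log-IMR are consistent with base 10:
  # log10(86.77) = 1.938
  p2 <- p; p2$y[1] <- 86.77
  expect_equal(log_outcome(p2, base = 10)$y[1], 1.938, tolerance = 5e-4)

  expect_equal(exp(log_outcome(p)$y), p$y, tolerance = 1e-12)

  p3 <- p; p3$y[2] <- 0
  expect_error(log_outcome(p3), "nonpositive outcome")
})

test_that("spatially lagged covariates equal explicit neighbour means per period", {
  w <- rook3()
  cfg <- synthetic_config(rows = 3, cols = 3, seed = 11)
  p <- simulate_panel(cfg, w)$panel
  K0 <- ncol(p$X)
  p2 <- add_spatial_lags(p, w, c("water_access", "sanitation"))
  expect_equal(ncol(p2$X), K0 + 2L)
  expect_true(all(c("W*water_access", "W*sanitation") %in% p2$covariate_names))

  for (t in seq_len(p$n_periods)) {
    rows <- (t - 1L) * 9L + 1:9
    x <- p$X[rows, "water_access"]
    oracle <- vapply(1:9, function(i) mean(x[w$neighbors[[i]]]), numeric(1))
    expect_equal(unname(p2$X[rows, "W*water_access"]), oracle,
                 tolerance = 1e-12)
  }

  pc <- p; pc$X[, "water_access"] <- 0.7
  expect_equal(unname(add_spatial_lags(pc, w, "water_access")$X[, "W*water_access"]),
               rep(0.7, 27), tolerance = 1e-14)

  expect_error(add_spatial_lags(p, w, "nope"), "unknown covariate")
  w2 <- row_standardize(build_lattice_weights(2, 2))
  expect_error(add_spatial_lags(p, w2, "water_access"), "region ids")
})

test_that("within transformation demeans by region, is idempotent, equals LSDV", {
  df <- make_long_panel(n = 10, t = 3, k = 2)
  p <- validate_panel(df, outcome = "y")

  pc <- p
  pc$y <- rep(5, length(pc$y))  # identical over time within each region
  expect_equal(within_transform(pc)$y, rep(0, length(pc$y)))

  wp <- within_transform(p)
  for (i in seq_len(p$n_regions))
    expect_equal(mean(wp$y[wp$region == i]), 0, tolerance = 1e-12)
  expect_equal(within_transform(wp), wp)   # idempotent

  # within-OLS equals least squares with one dummy per region
  b_within <- qr.coef(qr(wp$X), wp$y)
  expect_equal(unname(b_within), unname(lsdv_beta(p)), tolerance = 1e-10)
})

test_that("pooled OLS matches the normal equations and is order invariant", {
  df <- make_long_panel(n = 10, t = 5, k = 3, seed = 3)   # 50 x 3
  p <- validate_panel(df, outcome = "y")
  fit <- pooled_ols(p)
  X1 <- cbind(1, p$X)
  oracle <- solve(crossprod(X1), crossprod(X1, p$y))[, 1]
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-10)

  fit2 <- pooled_ols(validate_panel(df[sample(nrow(df)), ], outcome = "y"))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)

  # exact linear outcome: zero residuals, R2 = 1
  pe <- p; pe$y <- 2 + p$X %*% c(1, -1, 0.5)
  fe <- pooled_ols(pe)
  expect_equal(max(abs(fe$residuals)), 0, tolerance = 1e-10)
  expect_equal(fe$r2, 1, tolerance = 1e-12)

  # collinear design is rejected with the offending column named
  pc <- p; pc$X <- cbind(pc$X, x_dup = pc$X[, 1])
  pc$covariate_names <- colnames(pc$X)
  expect_error(pooled_ols(pc), "collinear.*x_dup")
})

test_that("fixed-effects estimator equals LSDV and recovers alpha and mu", {
  df <- make_long_panel(n = 8, t = 3, k = 2, seed = 5)
  p <- validate_panel(df, outcome = "y")
  fit <- fe_ols(p)
  expect_equal(fit$beta, lsdv_beta(p), tolerance = 1e-10)
  expect_equal(sum(fit$mu), 0, tolerance = 1e-10)
  expect_equal(fit$fitted + fit$residuals, p$y, tolerance = 1e-10)

  # alpha + mu_i reproduces the LSDV region intercepts
  dfl <- data.frame(y = p$y, region = factor(p$region),
                    as.data.frame(p$X))
  lf <- stats::lm(y ~ x1 + x2 + region, data = dfl)
  pred_lsdv <- unname(stats::fitted(lf))
  expect_equal(unname(fit$fitted), pred_lsdv, tolerance = 1e-10)

  pt <- p; pt$X[, 1] <- rep(1:p$n_regions, p$n_periods)  # time-invariant
  expect_error(fe_ols(pt), "within-region variation.*x1")
})

test_that("pooled and FE estimates coincide without regional heterogeneity", {
  cfg <- synthetic_config(rows = 10, cols = 10, process = "none",
                          sigma_mu = 0, seed = 21)
  p <- simulate_panel(cfg)$panel
  fp <- pooled_ols(p)
  ff <- fe_ols(p)
  expect_lt(max(abs(fp$beta[names(ff$beta)] - ff$beta) /
                  fp$std_errors[names(ff$beta)]), 3)
})

test_that("R-squared is monotone in added covariates and bounded", {
  df <- make_long_panel(n = 10, t = 3, k = 2, seed = 9)
  p1 <- validate_panel(df, outcome = "y", covariates = "x1")
  p2 <- validate_panel(df, outcome = "y", covariates = c("x1", "x2"))
  r1 <- pooled_ols(p1)$r2
  r2 <- pooled_ols(p2)$r2
  expect_gte(r2, r1)
  expect_true(r1 >= 0 && r2 <= 1)
})
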