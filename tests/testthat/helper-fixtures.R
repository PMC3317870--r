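# Shared fixtures: tiny lattices and hand-built panels, all generated in
# code at test time.

rook3 <- function() row_standardize(build_lattice_weights(3, 3, "rook"))

# Long-format data.frame for a small balanced panel with iid noise.
make_long_panel <- function(n = 6, t = 3, k = 2, seed = 7) {
  withr::with_seed(seed, {
    grid <- expand.grid(region_id = sprintf("r%02d", seq_len(n)),
                        period = sprintf("t%d", seq_len(t)),
                        stringsAsFactors = FALSE)
    X <- matrix(rnorm(nrow(grid) * k), ncol = k,
                dimnames = list(NULL, paste0("x", seq_len(k))))
    mu <- rnorm(n)
    beta <- seq_len(k)
    y <- 1 + X %*% beta + mu[match(grid$region_id, unique(grid$region_id))] +
      rnorm(nrow(grid), sd = 0.3)
    cbind(grid, data.frame(y = as.numeric(y)), as.data.frame(X))
  })
}

# Dummy-variable (LSDV) oracle for the within estimator, via stats::lm.
lsdv_beta <- function(p) {
  df <- data.frame(y = p$y, region = factor(p$region))
  df <- cbind(df, as.data.frame(p$X))
  covs <- make.names(colnames(p$X))
  names(df) <- c("y", "region", covs)
  fit <- stats::lm(stats::reformulate(c(covs, "region"), "y"), data = df)
  b <- stats::coef(fit)[covs]
  names(b) <- colnames(p$X)
  b
}
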