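# Small grids and cohorts used across the suite.

tiny_grid <- function(n = 8L, vox = 2) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- -vox * floor(n / 2)
  volume_grid(rep(n, 3L), aff)
}

random_gm <- function(grid, subject_id = "s1", seed = 1) {
  set.seed(seed)
  gm_volume(subject_id, grid,
            array(runif(prod(grid$shape), 0.2, 1), grid$shape))
}

# cohort with covariates but no imaging, n per group
toy_cohort <- function(n_per_group, groups = c("NC", "SCD"), seed = 42) {
  sizes <- stats::setNames(rep(n_per_group, length(groups)), groups)
  generate_cohort(sizes, rng_seed = seed)
}

# full-grid mask
all_mask <- function(grid) mask_volume(grid, array(TRUE, grid$shape))

# hand-rolled per-voxel OLS + t oracle via lm(), independent of the
# package's QR path
lm_oracle <- function(X, y, contrast) {
  fit <- stats::lm(y ~ X - 1)
  beta <- unname(stats::coef(fit))
  df <- length(y) - ncol(X)
  s2 <- sum(stats::residuals(fit)^2) / df
  se <- sqrt(s2 * drop(t(contrast) %*% solve(crossprod(X)) %*% contrast))
  tval <- sum(contrast * beta) / se
  list(beta = beta, sigma2 = s2, t = tval,
       p_pos = stats::pt(tval, df, lower.tail = FALSE))
}
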