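interaction_fixture <- function(n_per = 12, slopes = c(NC = 0.8, SCD = 0.3),
                                noise_sd = 0, grid = tiny_grid(10, 1.5),
                                rng = 30) {
  b <- array(TRUE, grid$shape)
  eff <- array(FALSE, grid$shape); eff[7:9, 4:7, 4:7] <- TRUE
  scen <- scn_scenario(grid = grid,
                       group_sizes = stats::setNames(rep(n_per, 2),
                                                     names(slopes)),
                       seed_region = build_sphere_mask(c(-4.5, 0, 0), 2, grid),
                       effect_regions = list(list(mask = mask_volume(grid, eff),
                                                  slopes = slopes)),
                       brain_mask = mask_volume(grid, b),
                       noise_sd = noise_sd, age_effect = 0)
  cohort <- generate_cohort(scen$group_sizes, rng_seed = rng)
  gen <- generate_gm_volumes(scen, cohort, rng_seed = rng + 1)
  list(scen = scen, cohort = cohort, gen = gen, eff = eff)
}

test_that("the interaction design is dummy-coded with a product column", {
  fx <- interaction_fixture()
  st <- extract_seed_values(fx$gen$volumes, fx$scen$seed_region)
  d <- build_interaction_design(fx$cohort, st, reference = "NC")
  expect_identical(dim(d$matrix), c(24L, 8L))
  expect_identical(colnames(d$matrix),
                   c("intercept", "seed", "group", "seed_x_group", "age",
                     "sex", "education", "etiv"))
  expect_equal(d$matrix[, "seed_x_group"],
               d$matrix[, "seed"] * d$matrix[, "group"])
  expect_equal(unname(d$matrix[, "group"]),
               as.numeric(fx$cohort$group != "NC"))
  one <- fx$cohort[fx$cohort$group == "NC", ]
  expect_error(build_interaction_design(one, st), "exactly two groups")
})

test_that("the noiseless interaction estimate is the exact slope difference", {
  fx <- interaction_fixture(noise_sd = 0)
  st <- extract_seed_values(fx$gen$volumes, fx$scen$seed_region)
  d <- build_interaction_design(fx$cohort, st, reference = "NC")
  amask <- gm_analysis_mask(fx$gen$volumes, 0.1,
                            exclude = fx$scen$seed_region)
  fit <- fit_voxelwise_glm(d, fx$gen$volumes, amask)
  beta_int <- fit$betas["seed_x_group", ]
  in_eff <- fx$eff[amask$data]
  expect_equal(unname(beta_int[in_eff]),
               rep(0.3 - 0.8, sum(in_eff)), tolerance = 1e-8)
  expect_equal(unname(beta_int[!in_eff]), rep(0, sum(!in_eff)),
               tolerance = 1e-8)
})

test_that("the interaction estimate matches a joint per-voxel lm oracle", {
  fx <- interaction_fixture(noise_sd = 0.05)
  st <- extract_seed_values(fx$gen$volumes, fx$scen$seed_region)
  d <- build_interaction_design(fx$cohort, st, reference = "NC")
  amask <- gm_analysis_mask(fx$gen$volumes, 0.1,
                            exclude = fx$scen$seed_region)
  fit <- fit_voxelwise_glm(d, fx$gen$volumes, amask)
  idx <- which(amask$data)[c(1, 5, 20)]
  cvec <- as.numeric(colnames(d$matrix) == "seed_x_group")
  for (v in idx) {
    y <- vapply(fx$gen$volumes, function(x) x$data[v], numeric(1))
    o <- lm_oracle(d$matrix, y, cvec)
    pos <- match(v, fit$voxel_index)
    expect_equal(unname(fit$betas[, pos]), o$beta, tolerance = 1e-8)
  }
})

test_that("the slope-difference map is negative where NC covaries more", {
  fx <- interaction_fixture(noise_sd = 0.02)
  st <- extract_seed_values(fx$gen$volumes, fx$scen$seed_region)
  d <- build_interaction_design(fx$cohort, st, reference = "NC")
  amask <- gm_analysis_mask(fx$gen$volumes, 0.1,
                            exclude = fx$scen$seed_region)
  fit <- fit_voxelwise_glm(d, fx$gen$volumes, amask)
  stat <- slope_difference_map(fit, "nc_greater")
  expect_true(all(stat$t[fx$eff & amask$data] < 0))

  # swapping the dummy coding negates the interaction t
  d2 <- build_interaction_design(fx$cohort, st, reference = "SCD")
  fit2 <- fit_voxelwise_glm(d2, fx$gen$volumes, amask)
  stat2 <- slope_difference_map(fit2, "nc_greater")
  expect_equal(stat2$t, -stat$t, tolerance = 1e-6)
})

test_that("smoothness estimates scale with voxel size and smoothing", {
  set.seed(40)
  grid1 <- mni_grid(c(24, 24, 24), 1.5)
  n <- 20
  raw <- lapply(1:n, function(i) array(rnorm(24^3), grid1$shape))
  sm <- lapply(raw, smooth_gaussian, fwhm_mm = 6, grid = grid1)
  make_fit <- function(vols, grid) {
    R <- t(vapply(vols, as.numeric, numeric(prod(grid$shape))))
    structure(list(residuals = R, voxel_index = seq_len(prod(grid$shape)),
                   mask = all_mask(grid), df = n - 1),
              class = "glm_fit")
  }
  est_smooth <- estimate_smoothness(make_fit(sm, grid1))
  est_raw <- estimate_smoothness(make_fit(raw, grid1))
  expect_true(all(est_smooth$fwhm_mm > est_raw$fwhm_mm))
  expect_true(all(abs(est_smooth$fwhm_mm - 6) < 0.9))  # 15%

  # same index-space data on a doubled voxel size: FWHM doubles in mm
  grid2 <- mni_grid(c(24, 24, 24), 3.0)
  est2 <- estimate_smoothness(make_fit(sm, grid2))
  expect_equal(est2$fwhm_mm, 2 * est_smooth$fwhm_mm, tolerance = 1e-8)
  expect_equal(est_smooth$resels,
               24^3 * 1.5^3 / prod(est_smooth$fwhm_mm))
})

test_that("the t-field EC density approaches the Gaussian density", {
  # convergence is pointwise; check around the voxel-level p = 0.01
  # threshold where the cluster-forming step evaluates the density
  u <- seq(1.8, 2.4, by = 0.1)
  rel <- abs(ec_density_t_3d(u, 1000) - ec_density_gaussian_3d(u)) /
    ec_density_gaussian_3d(u)
  expect_true(all(rel < 0.01))
  # and it converges monotonically in df at fixed u
  dfs <- c(20, 50, 200, 1000)
  err <- abs(ec_density_t_3d(2.326, dfs) - ec_density_gaussian_3d(2.326))
  expect_true(all(diff(err) < 0))
})

fake_stat <- function(tarr, grid, df = 30, direction = "nc_less") {
  structure(list(t = tarr, p = array(NA_real_, dim(tarr)), df = df,
                 tail = if (direction == "nc_less") "positive" else "negative",
                 direction = direction, grid = grid,
                 analysis_mask = mask_volume(grid, !is.na(tarr))),
            class = "stat_map")
}

fake_smoothness <- function(grid, fwhm = 6) {
  vol <- prod(grid$shape) * prod(grid$voxel_size_mm)
  structure(list(fwhm_mm = rep(fwhm, 3), resels = vol / fwhm^3,
                 search_volume_voxels = prod(grid$shape)),
            class = "smoothness_estimate")
}

test_that("corrected cluster p decreases with extent", {
  grid <- mni_grid(c(30, 30, 30), 1.5)
  tarr <- array(0, grid$shape)
  tarr[2:4, 2:4, 2:4] <- 10       # 27 voxels
  tarr[10:15, 10:15, 10:13] <- 10 # 144 voxels
  stat <- fake_stat(tarr, grid)
  inf <- grf_cluster_inference(stat, fake_smoothness(grid), min_extent = 1L)
  ext <- vapply(inf$all_clusters, `[[`, 0L, "extent")
  pc <- vapply(inf$all_clusters, `[[`, 0, "corrected_p")
  expect_equal(ext, c(144L, 27L))
  expect_lt(pc[1], pc[2])
  # every retained cluster satisfies both rules
  inf2 <- grf_cluster_inference(stat, fake_smoothness(grid), min_extent = 100L)
  for (cl in inf2$clusters) {
    expect_lt(cl$corrected_p, 0.05)
    expect_gt(cl$extent, 100)
  }
})

test_that("direction symmetry: nc_greater on T equals nc_less on -T", {
  grid <- mni_grid(c(20, 20, 20), 1.5)
  set.seed(50)
  tarr <- array(rnorm(20^3, 0, 2), grid$shape)
  s1 <- fake_stat(tarr, grid, direction = "nc_less")
  s2 <- fake_stat(-tarr, grid, direction = "nc_greater")
  i1 <- grf_cluster_inference(s1, fake_smoothness(grid, 4), min_extent = 1L)
  i2 <- grf_cluster_inference(s2, fake_smoothness(grid, 4), min_extent = 1L)
  expect_equal(lapply(i1$all_clusters, `[[`, "voxel_indices"),
               lapply(i2$all_clusters, `[[`, "voxel_indices"))
  expect_equal(i1$threshold_t, i2$threshold_t)
})
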