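make_design_cohort <- function(n, group = "NC", seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%02d", 1:n), group = group,
             age = rnorm(n, 65, 7), sex = rbinom(n, 1, 0.5),
             education = rnorm(n, 11, 4), etiv = rnorm(n, 1.4e6, 1e5))
}

seed_table_for <- function(cohort, seed = 2) {
  set.seed(seed)
  structure(list(seed_name = "toy",
                 values = stats::setNames(rnorm(nrow(cohort), 0.5, 0.1),
                                          cohort$subject_id)),
            class = "seed_table")
}

test_that("within-group design has the six named columns, full rank", {
  cohort <- make_design_cohort(10)
  cohort$sex <- rep(0:1, 5)
  d <- build_within_group_design(cohort, seed_table_for(cohort))
  expect_identical(dim(d$matrix), c(10L, 6L))
  expect_identical(colnames(d$matrix),
                   c("intercept", "seed", "age", "sex", "education", "etiv"))
  expect_equal(qr(d$matrix)$rank, 6)
})

test_that("a single-sex group drops the constant sex column with a warning", {
  cohort <- make_design_cohort(10)
  cohort$sex <- 0
  expect_warning(d <- build_within_group_design(cohort, seed_table_for(cohort)),
                 "constant 'sex'")
  expect_identical(ncol(d$matrix), 5L)
  expect_false("sex" %in% colnames(d$matrix))
})

test_that("duplicated covariates make the design rank deficient", {
  cohort <- make_design_cohort(10)
  cohort$sex <- rep(0:1, 5)
  cohort$etiv <- cohort$education  # duplicate column
  expect_error(build_within_group_design(cohort, seed_table_for(cohort)),
               "rank deficient")
})

test_that("noise-free data are reproduced exactly by the voxelwise fit", {
  grid <- tiny_grid(6, 2)
  cohort <- make_design_cohort(12)
  cohort$sex <- rep(0:1, 6)
  st <- seed_table_for(cohort)
  d <- build_within_group_design(cohort, st)
  set.seed(9)
  B <- matrix(rnorm(6 * prod(grid$shape)), 6)  # generating coefficients
  vols <- lapply(seq_len(12), function(i) {
    gm_volume(cohort$subject_id[i], grid,
              array(drop(d$matrix[i, ] %*% B), grid$shape))
  })
  fit <- fit_voxelwise_glm(d, vols, all_mask(grid))
  expect_equal(unname(fit$betas), unname(B), tolerance = 1e-8)
  expect_lt(max(fit$sigma2), 1e-16)
  expect_equal(fit$df, 6)
})

test_that("betas, t and p match an independent per-voxel lm oracle", {
  grid <- volume_grid(c(5, 1, 1), diag(4))
  cohort <- make_design_cohort(14, seed = 3)
  cohort$sex <- rep(0:1, 7)
  st <- seed_table_for(cohort, seed = 4)
  d <- build_within_group_design(cohort, st)
  set.seed(5)
  vols <- lapply(seq_len(14), function(i)
    gm_volume(cohort$subject_id[i], grid, array(rnorm(5, 0.5, 0.2), c(5, 1, 1))))
  fit <- fit_voxelwise_glm(d, vols, all_mask(grid))
  stat <- t_contrast(fit, "seed", "positive")
  cvec <- as.numeric(colnames(d$matrix) == "seed")
  for (v in 1:5) {
    y <- vapply(vols, function(x) x$data[v, 1, 1], numeric(1))
    o <- lm_oracle(d$matrix, y, cvec)
    expect_equal(unname(fit$betas[, v]), o$beta, tolerance = 1e-8)
    expect_equal(fit$sigma2[v], o$sigma2, tolerance = 1e-8)
    expect_equal(stat$t[v, 1, 1], o$t, tolerance = 1e-8)
    expect_equal(stat$p[v, 1, 1], o$p_pos, tolerance = 1e-8)
  }
})

test_that("df equals n minus p", {
  grid <- volume_grid(c(2, 1, 1), diag(4))
  cohort <- make_design_cohort(7, seed = 8)
  cohort$sex <- c(0, 1, 0, 1, 0, 1, 0)
  d <- build_within_group_design(cohort, seed_table_for(cohort, 9))
  vols <- lapply(seq_len(7), function(i)
    gm_volume(cohort$subject_id[i], grid, array(rnorm(2, 0.5, 0.1), c(2, 1, 1))))
  expect_equal(fit_voxelwise_glm(d, vols, all_mask(grid))$df, 1)
  expect_error(fit_voxelwise_glm(d, vols[1:6], all_mask(grid)),
               "one volume per design row")
})

test_that("contrast sign symmetry and two-sided p identity hold", {
  grid <- volume_grid(c(6, 1, 1), diag(4))
  cohort <- make_design_cohort(15, seed = 13)
  cohort$sex <- rep(c(0, 1, 0), 5)
  d <- build_within_group_design(cohort, seed_table_for(cohort, 14))
  set.seed(15)
  vols <- lapply(seq_len(15), function(i)
    gm_volume(cohort$subject_id[i], grid, array(rnorm(6, 0.5, 0.2), c(6, 1, 1))))
  fit <- fit_voxelwise_glm(d, vols, all_mask(grid))
  cvec <- as.numeric(colnames(d$matrix) == "seed")
  pos <- t_contrast(fit, cvec, "positive")
  neg <- t_contrast(fit, -cvec, "positive")
  expect_equal(neg$t, -pos$t)
  two <- t_contrast(fit, cvec, "two_sided")
  ptail <- pmin(pos$p, t_contrast(fit, cvec, "negative")$p)
  expect_equal(two$p, 2 * ptail)
})

test_that("BH rejection matches exhaustive step-up enumeration", {
  grid <- volume_grid(c(4, 1, 1), diag(4))
  stat <- structure(list(
    t = array(1, c(4, 1, 1)), p = array(c(0.001, 0.008, 0.039, 0.041), c(4, 1, 1)),
    df = 10, tail = "positive", grid = grid,
    analysis_mask = mask_volume(grid, array(TRUE, c(4, 1, 1)))),
    class = "stat_map")
  sig <- fdr_threshold(stat, 0.05)
  # brute force: largest k with p_(k) <= k q / m
  p <- c(0.001, 0.008, 0.039, 0.041)
  ks <- which(sort(p) <= seq_along(p) * 0.05 / length(p))
  k <- max(ks)
  expect_equal(which(sig$data), order(p)[seq_len(k)])
  # cross-check against stats::p.adjust
  expect_equal(sort(which(sig$data)),
               sort(which(p.adjust(p, "BH") <= 0.05)))
})

test_that("BH keeps everything when all p equal q/2 and nothing below q/m", {
  grid <- volume_grid(c(8, 1, 1), diag(4))
  mk <- mask_volume(grid, array(TRUE, c(8, 1, 1)))
  st <- function(p) structure(list(t = array(1, c(8, 1, 1)),
                                   p = array(p, c(8, 1, 1)), df = 10,
                                   tail = "positive", grid = grid,
                                   analysis_mask = mk), class = "stat_map")
  expect_equal(fdr_threshold(st(rep(0.025, 8)), 0.05)$n_voxels, 8)
  # every ordered p exceeds its step-up bound k q / m -> nothing rejected
  expect_equal(fdr_threshold(st(c(0.05, 0.2, 0.5, 0.8, 0.9, 0.93, 0.96, 0.99)),
                             0.05)$n_voxels, 0)
})

test_that("the extent filter is strict and conserving", {
  grid <- mni_grid(c(24, 24, 48), 1.5)
  data <- array(FALSE, grid$shape)
  data[3:12, 3:7, 1:3] <- TRUE         # 150 voxels
  data[3:13, 3:11, 10] <- TRUE         # 99 voxels
  cl <- extent_filter(mask_volume(grid, data), 100L)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$extent, 150)

  exact <- array(FALSE, grid$shape)
  exact[1:10, 1:10, 20] <- TRUE        # exactly 100
  expect_length(extent_filter(mask_volume(grid, exact), 100L), 0)

  allcl <- label_clusters(mask_volume(grid, data))
  expect_equal(sum(vapply(allcl, `[[`, 0L, "extent")), sum(data))
})

test_that("a seed covaries positively with its own neighbourhood", {
  grid <- mni_grid(c(24, 24, 24), 1.5)
  b <- array(FALSE, grid$shape); b[5:20, 5:20, 5:20] <- TRUE
  scen <- scn_scenario(grid = grid, group_sizes = c(NC = 15L),
                       seed_region = build_sphere_mask(c(0, 0, 0), 3, grid),
                       brain_mask = mask_volume(grid, b),
                       noise_sd = 0.05)
  cohort <- generate_cohort(c(NC = 15L), rng_seed = 20)
  gen <- generate_gm_volumes(scen, cohort, rng_seed = 21)
  # smoothing spreads the injected seed signal into adjacent voxels
  sm <- lapply(gen$volumes, smooth_gaussian, fwhm_mm = 6)
  stab <- extract_seed_values(sm, scen$seed_region)
  d <- build_within_group_design(cohort, stab)
  amask <- gm_analysis_mask(sm, 0.1, exclude = scen$seed_region)
  fit <- fit_voxelwise_glm(d, sm, amask)
  stat <- t_contrast(fit, "seed", "positive")
  ring <- build_sphere_mask(c(0, 0, 0), 6, grid)$data &
          !scen$seed_region$data & amask$data
  expect_true(all(stat$t[ring] > 0))
})
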