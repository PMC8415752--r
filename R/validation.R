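#' Slope-difference recovery study
#'
#' Repeatedly simulates a two-group cohort whose effect-region voxels
#' follow the seed value with different slopes per group, fits the
#' dummy-coded interaction model, and averages the estimated interaction
#' coefficient over the effect region. Defaults are the validation
#' conditions used throughout: 48^3 grid at 1.5 mm, 40 subjects per
#' group, slopes 0.8 (reference) vs 0.3 (patient), noise SD 0.1 before
#' 6-mm smoothing.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n_per_group subjects per group.
#' @param slopes named numeric(2): reference and patient slope; the first
#'   name is the reference group.
#' @param grid simulation grid.
#' @param noise_sd,noise_fwhm_mm noise parameters.
#' @param rng_seed base seed; independent per-replicate seeds are drawn from it.
#' @return list: `estimates` (per replicate mean interaction beta over
#'   effect voxels), `mean_estimate`, `truth` (patient minus reference
#'   slope).
#' @export
slope_recovery_study <- function(n_replicates = 50, n_per_group = 40,
                                 slopes = c(NC = 0.8, SCD = 0.3),
                                 grid = mni_grid(),
                                 noise_sd = 0.1, noise_fwhm_mm = 6,
                                 rng_seed = 1L) {
  sizes <- stats::setNames(rep(n_per_group, 2L), names(slopes))
  scen <- scn_scenario(grid = grid, group_sizes = sizes,
                       noise_sd = noise_sd, noise_fwhm_mm = noise_fwhm_mm)
  scen$effect_regions[[1]]$slopes <- slopes
  truth <- unname(slopes[2] - slopes[1])
  est <- numeric(n_replicates)
  set.seed(rng_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(sizes, rng_seed = rep_seeds[2L * r - 1L])
    gen <- generate_gm_volumes(scen, cohort, rng_seed = rep_seeds[2L * r])
    st <- extract_seed_values(gen$volumes, scen$seed_region)
    design <- build_interaction_design(cohort, st,
                                       reference = names(slopes)[1])
    amask <- gm_analysis_mask(gen$volumes, exclude = scen$seed_region)
    fit <- fit_voxelwise_glm(design, gen$volumes, amask)
    in_eff <- scen$effect_regions[[1]]$mask$data[amask$data]
    est[r] <- mean(fit$betas["seed_x_group", in_eff])
  }
  list(estimates = est, mean_estimate = mean(est), truth = truth)
}

#' Null calibration study: cluster-level RFT and voxel-level BH
#'
#' Simulates cohorts with no seed effect anywhere (all slopes zero) and
#' measures, per replicate, (i) whether the two-direction interaction
#' analysis yields any cluster with RFT-corrected p below `cluster_alpha`
#' and (ii) whether the within-group positive covariance map of the
#' reference group rejects any voxel under Benjamini-Hochberg at `fdr_q`.
#' Both empirical rates should stay near (at or below) their nominal
#' levels.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n_per_group subjects per group (two groups).
#' @param grid simulation grid.
#' @param cluster_forming_p two-tailed voxel-level threshold.
#' @param cluster_alpha cluster-level alpha.
#' @param fdr_q voxel-level FDR level for the within-group map.
#' @param noise_sd,noise_fwhm_mm noise parameters.
#' @param rng_seed base seed.
#' @return list: `grf_family_wise_rate`, `bh_any_rejection_rate`,
#'   per-replicate logicals `grf_any`, `bh_any`, and `n_replicates`.
#' @export
null_calibration_study <- function(n_replicates = 200, n_per_group = 20,
                                   grid = mni_grid(),
                                   cluster_forming_p = 0.01,
                                   cluster_alpha = 0.05, fdr_q = 0.05,
                                   noise_sd = 0.1, noise_fwhm_mm = 6,
                                   rng_seed = 1L) {
  sizes <- c(NC = n_per_group, SCD = n_per_group)
  scen <- scn_scenario(grid = grid, group_sizes = sizes,
                       noise_sd = noise_sd, noise_fwhm_mm = noise_fwhm_mm)
  grf_any <- logical(n_replicates)
  bh_any <- logical(n_replicates)
  set.seed(rng_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(sizes, rng_seed = rep_seeds[2L * r - 1L])
    gen <- generate_gm_volumes(scen, cohort, rng_seed = rep_seeds[2L * r])
    st <- extract_seed_values(gen$volumes, scen$seed_region)
    amask <- gm_analysis_mask(gen$volumes, exclude = scen$seed_region)

    # cluster-level RFT on the interaction map, both directions
    design <- build_interaction_design(cohort, st, reference = "NC")
    fit <- fit_voxelwise_glm(design, gen$volumes, amask)
    smoothness <- estimate_smoothness(fit)
    hit <- FALSE
    for (direction in c("nc_greater", "nc_less")) {
      stat <- slope_difference_map(fit, direction)
      inf <- grf_cluster_inference(stat, smoothness, cluster_forming_p,
                                   cluster_alpha, min_extent = 1L)
      if (length(inf$clusters) > 0L) hit <- TRUE
    }
    grf_any[r] <- hit

    # voxel-level BH on the reference group's positive covariance map
    nc <- cohort$group == "NC"
    d_nc <- build_within_group_design(cohort[nc, ], st)
    fit_nc <- fit_voxelwise_glm(d_nc, gen$volumes[nc], amask)
    stat_nc <- t_contrast(fit_nc, "seed", "positive")
    bh_any[r] <- fdr_threshold(stat_nc, fdr_q)$n_voxels > 0L
  }
  list(grf_family_wise_rate = mean(grf_any),
       bh_any_rejection_rate = mean(bh_any),
       grf_any = grf_any, bh_any = bh_any, n_replicates = n_replicates)
}

#' Smoothness-estimator recovery
#'
#' Simulates unit-variance white noise smoothed to a known FWHM,
#' residualizes it against a nuisance design (so the estimator sees
#' genuine regression residuals) and returns the estimated per-axis
#' FWHM.
#'
#' @param n_images number of noise images (residual degrees of freedom
#'   scale with it).
#' @param fwhm_mm true smoothing kernel FWHM.
#' @param grid simulation grid.
#' @param rng_seed seed.
#' @return list: `fwhm_mm` (estimated, 3), `true_fwhm_mm`, `resels`.
#' @export
smoothness_recovery_study <- function(n_images = 40, fwhm_mm = 6,
                                      grid = mni_grid(), rng_seed = 1L) {
  set.seed(rng_seed)
  sig <- fwhm_to_sigma(fwhm_mm) / grid$voxel_size_mm
  V <- prod(grid$shape)
  R <- matrix(0, n_images, V)
  for (i in seq_len(n_images))
    R[i, ] <- as.numeric(smooth_array(array(stats::rnorm(V), grid$shape), sig))
  X <- cbind(1, stats::rnorm(n_images))  # nuisance design to residualize
  R <- R - X %*% qr.coef(qr(X), R)
  fit <- structure(list(residuals = R, voxel_index = seq_len(V),
                        mask = mask_volume(grid, array(TRUE, grid$shape)),
                        df = n_images - 2L),
                   class = "glm_fit")
  est <- estimate_smoothness(fit)
  list(fwhm_mm = est$fwhm_mm, true_fwhm_mm = fwhm_mm, resels = est$resels)
}
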