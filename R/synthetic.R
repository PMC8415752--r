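#' Reference cohort moments
#'
#' Group-wise demographic and neuropsychological moments (mean, SD) and
#' sex counts used by the cohort simulator: four groups along the
#' clinical continuum — normal controls (NC), subjective cognitive
#' decline (SCD), amnestic mild cognitive impairment (aMCI) and
#' Alzheimer's disease (AD) — with sizes 42/35/43/41. eTIV is in mm^3.
#'
#' @return data.frame, one row per group.
#' @export
cohort_reference_moments <- function() {
  data.frame(
    group = c("NC", "SCD", "aMCI", "AD"),
    n = c(42L, 35L, 43L, 41L),
    age_mean = c(64.24, 64.54, 67.47, 68.88),
    age_sd = c(6.16, 7.29, 10.03, 7.86),
    men = c(15L, 15L, 21L, 17L),
    women = c(27L, 20L, 22L, 24L),
    education_mean = c(11.17, 11.83, 10.44, 9.68),
    education_sd = c(5.61, 3.67, 4.96, 4.71),
    etiv_mean = c(1.40e6, 1.44e6, 1.47e6, 1.40e6),
    etiv_sd = c(0.12e6, 0.14e6, 0.16e6, 0.13e6),
    moca_mean = c(26.02, 25.26, 19.67, 13.10),
    moca_sd = c(2.95, 2.27, 4.28, 5.46),
    avlt_immediate_mean = c(9.32, 8.54, 5.84, 3.53),
    avlt_immediate_sd = c(1.94, 1.82, 1.34, 1.58),
    avlt_delayed_mean = c(10.43, 8.86, 3.19, 0.98),
    avlt_delayed_sd = c(2.31, 2.78, 2.81, 1.60),
    avlt_recognition_mean = c(12.07, 11.37, 6.58, 3.51),
    avlt_recognition_sd = c(2.13, 2.20, 4.28, 3.08),
    stringsAsFactors = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a cohort table
#'
#' Draws demographics and cognitive scores per group from normal
#' distributions with the reference moments, clipped to instrument /
#' plausibility ranges (age 40-95 y, education 0-22 y, MoCA 0-30, AVLT
#' immediate and delayed recall 0-15, AVLT recognition 0-24). Sex is
#' Bernoulli with the group's observed male fraction (1 = male). CDR is
#' set by group (NC and SCD 0, aMCI 0.5, AD 1-3); HAMD and Hachinski
#' scores are drawn in the eligible range.
#'
#' @param group_sizes named integer vector; default the reference sizes
#'   `c(NC = 42, SCD = 35, aMCI = 43, AD = 41)`.
#' @param rng_seed integer seed; the cohort is a deterministic function
#'   of it.
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `age`, `sex`, `education`, `etiv`, `moca`, `avlt_immediate`,
#'   `avlt_delayed`, `avlt_recognition`, `cdr`, `hamd`, `hachinski`.
#' @export
generate_cohort <- function(group_sizes = c(NC = 42L, SCD = 35L, aMCI = 43L,
                                            AD = 41L),
                            rng_seed = 1L) {
  stopifnot(all(group_sizes >= 2L), !is.null(names(group_sizes)))
  mom <- cohort_reference_moments()
  set.seed(rng_seed)
  rows <- lapply(names(group_sizes), function(g) {
    n <- group_sizes[[g]]
    m <- mom[match(g, mom$group), ]
    if (is.na(m$group)) stop("no reference moments for group ", g)
    data.frame(
      subject_id = sprintf("%s%03d", g, seq_len(n)),
      group = g,
      age = clamp(stats::rnorm(n, m$age_mean, m$age_sd), 40, 95),
      sex = stats::rbinom(n, 1L, m$men / (m$men + m$women)),
      education = clamp(stats::rnorm(n, m$education_mean, m$education_sd), 0, 22),
      etiv = clamp(stats::rnorm(n, m$etiv_mean, m$etiv_sd), 1.0e6, 2.0e6),
      moca = clamp(stats::rnorm(n, m$moca_mean, m$moca_sd), 0, 30),
      avlt_immediate = clamp(stats::rnorm(n, m$avlt_immediate_mean,
                                          m$avlt_immediate_sd), 0, 15),
      avlt_delayed = clamp(stats::rnorm(n, m$avlt_delayed_mean,
                                        m$avlt_delayed_sd), 0, 15),
      avlt_recognition = clamp(stats::rnorm(n, m$avlt_recognition_mean,
                                            m$avlt_recognition_sd), 0, 24),
      cdr = switch(g, NC = 0, SCD = 0, aMCI = 0.5,
                   AD = sample(c(1, 2, 3), n, TRUE, c(0.5, 0.3, 0.2)),
                   0),
      hamd = sample(0:10, n, TRUE),
      hachinski = sample(0:3, n, TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

moca_education_threshold <- function(education_years) {
  ifelse(education_years <= 6, 19, ifelse(education_years <= 12, 22, 24))
}

#' Rule-based diagnostic classification
#'
#' Applies the study-style inclusion rules to one subject record:
#' \itemize{
#'   \item excluded when HAMD > 24 or Hachinski > 4;
#'   \item MoCA is "normal" when strictly above the education-adjusted
#'     threshold (19 for primary school or below, <= 6 y; 22 for
#'     secondary schooling, 7-12 y; 24 for university, > 12 y);
#'   \item a memory test (AVLT-delayed recall, AVLT recognition) is
#'     abnormal at level s when the score falls strictly below the NC
#'     mean minus s SDs;
#'   \item AD: CDR >= 1. aMCI: CDR 0.5, MoCA below the education
#'     threshold, and at least one memory test abnormal at 1.5 SD.
#'     SCD: CDR 0, normal MoCA, exactly one memory test abnormal at
#'     1 SD. NC: CDR 0, normal MoCA, no abnormal memory test at 1 SD.
#'     Anything else is "unclassified".
#' }
#'
#' @param record one-row data.frame or list with `moca`, `education`,
#'   `avlt_delayed`, `avlt_recognition`, `cdr`, `hamd`, `hachinski`.
#' @param nc_reference list with elements `avlt_delayed` and
#'   `avlt_recognition`, each `c(mean, sd)` of NC performance; default
#'   the reference moments.
#' @return list: `label` ("NC", "SCD", "aMCI", "AD", "excluded",
#'   "unclassified") and logical `flags` naming which criteria fired.
#' @export
classify_diagnosis <- function(record, nc_reference = NULL) {
  need <- c("moca", "education", "avlt_delayed", "avlt_recognition", "cdr",
            "hamd", "hachinski")
  miss <- need[!vapply(need, function(f) !is.null(record[[f]]) && !is.na(record[[f]]),
                       logical(1))]
  if (length(miss)) stop("missing fields: ", paste(miss, collapse = ", "))
  if (is.null(nc_reference)) {
    m <- cohort_reference_moments()[1, ]
    nc_reference <- list(avlt_delayed = c(m$avlt_delayed_mean, m$avlt_delayed_sd),
                         avlt_recognition = c(m$avlt_recognition_mean,
                                              m$avlt_recognition_sd))
  }
  stopifnot(all(is.finite(unlist(nc_reference))))
  abn <- function(score, ref, sds) score < ref[1] - sds * ref[2]
  a1 <- c(delayed = abn(record$avlt_delayed, nc_reference$avlt_delayed, 1),
          recognition = abn(record$avlt_recognition,
                            nc_reference$avlt_recognition, 1))
  a15 <- c(delayed = abn(record$avlt_delayed, nc_reference$avlt_delayed, 1.5),
           recognition = abn(record$avlt_recognition,
                             nc_reference$avlt_recognition, 1.5))
  moca_normal <- record$moca > moca_education_threshold(record$education)
  excluded <- record$hamd > 24 || record$hachinski > 4
  label <- if (excluded) {
    "excluded"
  } else if (record$cdr >= 1) {
    "AD"
  } else if (record$cdr == 0.5 && !moca_normal && any(a15)) {
    "aMCI"
  } else if (record$cdr == 0 && moca_normal && sum(a1) == 1L) {
    "SCD"
  } else if (record$cdr == 0 && moca_normal && sum(a1) == 0L) {
    "NC"
  } else {
    "unclassified"
  }
  list(label = label,
       flags = list(excluded = excluded, moca_normal = moca_normal,
                    abnormal_1sd = a1, abnormal_1.5sd = a15))
}

#' Synthetic covariance scenario
#'
#' Defines the ground truth for simulated GM volumes: a seed region whose
#' voxels carry each subject's latent seed value, effect regions whose
#' voxels follow the seed value linearly with group-specific slopes, an
#' age effect, and spatially smoothed Gaussian noise. Defaults are the
#' simulation conditions used throughout the validation suite: a 48^3
#' grid at 1.5 mm, latent seed values N(0.5, 0.1), baseline GM density
#' 0.5 inside a brain box kept clear of the grid edge, noise SD 0.1
#' (before smoothing) and noise FWHM 6 mm.
#'
#' @param grid a [volume_grid], default [mni_grid()].
#' @param group_sizes named sizes, default the reference cohort.
#' @param seed_region [mask_volume]; default a 4-mm sphere at (-12,0,0).
#' @param effect_regions list of `list(mask =, slopes = named numeric per
#'   group)`; default one 6-mm sphere at (12,0,0) with slope 0 everywhere
#'   (a null scenario until slopes are set).
#' @param brain_mask [mask_volume] of nonzero GM; default an inner box
#'   with an 8-voxel margin.
#' @param baseline GM density inside the brain, default 0.5.
#' @param latent_mean,latent_sd latent seed value distribution.
#' @param age_effect GM density change per year of age (centred at 65 y),
#'   default -0.002.
#' @param noise_sd white-noise SD before smoothing, default 0.1.
#' @param noise_fwhm_mm smoothing FWHM of the noise field, default 6.
#' @return object of class `scn_scenario`.
#' @export
scn_scenario <- function(grid = mni_grid(),
                         group_sizes = c(NC = 42L, SCD = 35L, aMCI = 43L,
                                         AD = 41L),
                         seed_region = NULL, effect_regions = NULL,
                         brain_mask = NULL, baseline = 0.5,
                         latent_mean = 0.5, latent_sd = 0.1,
                         age_effect = -0.002, noise_sd = 0.1,
                         noise_fwhm_mm = 6) {
  stopifnot(all(group_sizes >= 2L), noise_sd >= 0)
  if (is.null(brain_mask)) {
    b <- array(FALSE, grid$shape)
    mar <- 8L
    b[(mar + 1):(grid$shape[1] - mar), (mar + 1):(grid$shape[2] - mar),
      (mar + 1):(grid$shape[3] - mar)] <- TRUE
    brain_mask <- mask_volume(grid, b)
  }
  mid <- pmax(round(grid$shape / 2), 1L)
  at_frac <- function(fx) {
    voxel_to_mni(grid, c(max(round(grid$shape[1] * fx), 1L), mid[2], mid[3]))
  }
  if (is.null(seed_region))
    seed_region <- build_sphere_mask(at_frac(0.3), 4, grid)
  if (is.null(effect_regions))
    effect_regions <- list(list(mask = build_sphere_mask(at_frac(0.7), 6, grid),
                                slopes = stats::setNames(
                                  rep(0, length(group_sizes)),
                                  names(group_sizes))))
  for (er in effect_regions) {
    stopifnot(inherits(er$mask, "mask_volume"),
              all(names(group_sizes) %in% names(er$slopes)))
    stop_if_grid_mismatch(er$mask$grid, grid, "effect region")
  }
  stop_if_grid_mismatch(seed_region$grid, grid, "seed region")
  stop_if_grid_mismatch(brain_mask$grid, grid, "brain mask")
  structure(list(grid = grid, group_sizes = group_sizes,
                 seed_region = seed_region, effect_regions = effect_regions,
                 brain_mask = brain_mask, baseline = baseline,
                 latent_mean = latent_mean, latent_sd = latent_sd,
                 age_effect = age_effect, noise_sd = noise_sd,
                 noise_fwhm_mm = noise_fwhm_mm),
            class = "scn_scenario")
}

#' Simulate GM volumes with known covariance structure
#'
#' Per subject: a latent seed value s ~ N(latent_mean, latent_sd) is
#' drawn; voxels get baseline + age_effect (age - 65) + slope(group) x
#' (s - latent_mean) in each effect region, plus a Gaussian noise field
#' (white noise of SD `noise_sd`, smoothed to `noise_fwhm_mm`) inside
#' the brain mask. Seed-region voxels are then set to s exactly, so the
#' mask-mean extraction path recovers the latent value and the remaining
#' voxels are independent of it under a null scenario.
#'
#' @param scenario an [scn_scenario].
#' @param cohort cohort data.frame (provides `subject_id`, `group`,
#'   `age`); group sizes need not match the scenario's defaults.
#' @param rng_seed integer seed; volumes are deterministic given it.
#' @return list with `volumes` (list of [gm_volume], cohort order) and
#'   `truth` (list: `latent` named per subject, `slopes` per region,
#'   `scenario`).
#' @export
generate_gm_volumes <- function(scenario, cohort, rng_seed = 1L) {
  grid <- scenario$grid
  set.seed(rng_seed)
  sig_vox <- fwhm_to_sigma(scenario$noise_fwhm_mm) / grid$voxel_size_mm
  latent <- stats::setNames(
    stats::rnorm(nrow(cohort), scenario$latent_mean, scenario$latent_sd),
    cohort$subject_id)
  brain <- scenario$brain_mask$data
  base <- array(0, grid$shape)
  base[brain] <- scenario$baseline
  volumes <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    vol <- base
    vol[brain] <- vol[brain] + scenario$age_effect * (cohort$age[i] - 65)
    s <- latent[[i]]
    for (er in scenario$effect_regions) {
      slope <- er$slopes[[as.character(cohort$group[i])]]
      vol[er$mask$data] <- vol[er$mask$data] +
        slope * (s - scenario$latent_mean)
    }
    if (scenario$noise_sd > 0) {
      noise <- smooth_array(array(stats::rnorm(prod(grid$shape), 0,
                                               scenario$noise_sd),
                                  grid$shape), rep_len(sig_vox, 3))
      vol[brain] <- vol[brain] + noise[brain]
    }
    vol[scenario$seed_region$data] <- s
    vol[vol < 0] <- 0
    volumes[[i]] <- gm_volume(cohort$subject_id[i], grid, vol)
  }
  truth <- list(latent = latent,
                slopes = lapply(scenario$effect_regions, `[[`, "slopes"),
                scenario = scenario)
  list(volumes = volumes, truth = truth)
}
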