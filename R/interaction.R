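#' Slope-difference (interaction) statistic map
#'
#' T map for the seed-by-group interaction coefficient of a dummy-coded
#' joint model. With the reference (NC) group coded 0, a negative
#' interaction t means the patient group's covariance slope is below the
#' reference slope; direction `"nc_greater"` therefore selects the
#' negative tail and `"nc_less"` the positive tail, matching the sign of
#' the reported peak intensities.
#'
#' @param fit `glm_fit` from an interaction design.
#' @param direction `"nc_greater"` or `"nc_less"`.
#' @return a `stat_map` (tail set to the direction's tail) with a
#'   `direction` field.
#' @export
slope_difference_map <- function(fit, direction = c("nc_greater", "nc_less")) {
  direction <- match.arg(direction)
  if (!"seed_x_group" %in% colnames(fit$design$matrix))
    stop("fit does not come from an interaction design")
  stat <- t_contrast(fit, "seed_x_group",
                     tail = if (direction == "nc_greater") "negative" else "positive")
  stat$direction <- direction
  stat
}

#' Residual-based smoothness of a fitted map
#'
#' Estimates the per-axis FWHM of the error field from the spatial
#' derivatives of the normalized residuals: with e_i(v) = r_i(v) /
#' sqrt(sum_i r_i(v)^2), the summed squared forward difference along axis
#' k estimates 2(1 - rho_k), the variance of the derivative of a
#' unit-variance field per voxel step; FWHM_k = sqrt(4 ln 2 / lambda_k)
#' with lambda_k in mm^-2. Resels are the mask volume divided by the
#' product of the FWHMs.
#'
#' @param fit a `glm_fit` (residuals retained).
#' @param analysis_mask mask over which smoothness is pooled; defaults to
#'   the fit's mask.
#' @param grid grid; defaults to the mask's.
#' @return object of class `smoothness_estimate` with `fwhm_mm` (3),
#'   `resels`, `search_volume_voxels`.
#' @export
estimate_smoothness <- function(fit, analysis_mask = fit$mask,
                                grid = analysis_mask$grid) {
  idx <- which(analysis_mask$data)
  bb <- apply(arrayInd(idx, grid$shape), 2, range)
  if (any(bb[2, ] - bb[1, ] < 2))
    stop("mask bounding box too small for smoothness estimation")
  pos <- match(idx, fit$voxel_index)
  if (anyNA(pos)) stop("analysis_mask must be a subset of the fitted mask")
  R <- fit$residuals[, pos, drop = FALSE]
  ss <- colSums(R^2)
  usable <- ss > 0
  idx <- idx[usable]
  E <- R[, usable, drop = FALSE] *
    rep(1 / sqrt(ss[usable]), each = nrow(R))  # unit sum-of-squares per voxel
  dm <- grid$shape
  ijk <- arrayInd(idx, dm)
  # position-in-E lookup for each grid voxel (0 = not usable)
  posmap <- array(0L, dm)
  posmap[idx] <- seq_along(idx)
  stride <- c(1L, dm[1], dm[1] * dm[2])
  lambda <- numeric(3)
  for (ax in 1:3) {
    interior <- ijk[, ax] < dm[ax]
    nb <- posmap[idx[interior] + stride[ax]]
    a <- which(interior)[nb > 0L]
    b <- nb[nb > 0L]
    if (length(a) == 0L) stop("no valid voxel pairs along axis ", ax)
    dd <- colSums((E[, b, drop = FALSE] - E[, a, drop = FALSE])^2)
    lambda[ax] <- mean(dd) / grid$voxel_size_mm[ax]^2
  }
  fwhm <- sqrt(4 * log(2) / lambda)
  vol_mm3 <- length(idx) * prod(grid$voxel_size_mm)
  structure(list(fwhm_mm = fwhm, resels = vol_mm3 / prod(fwhm),
                 search_volume_voxels = length(idx)),
            class = "smoothness_estimate")
}

#' 3D Euler-characteristic density of a t field
#'
#' Worsley's 3D EC density for a unit-roughness t field with `df` degrees
#' of freedom, evaluated at threshold `u`. As `df` grows it converges to
#' the Gaussian EC density [ec_density_gaussian_3d()].
#'
#' @param u threshold.
#' @param df degrees of freedom.
#' @return density per resel.
#' @export
ec_density_t_3d <- function(u, df) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 *
    ((df - 1) / df * u^2 - 1) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' 3D Euler-characteristic density of a Gaussian field
#' @param u threshold.
#' @return density per resel.
#' @export
ec_density_gaussian_3d <- function(u) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
}

#' Random-field-theory cluster-level inference
#'
#' Stationary-field cluster correction for a directional t map:
#' \enumerate{
#'   \item voxel threshold u = upper t quantile at the per-tail
#'     cluster-forming p (`cluster_forming_p / 2` when `two_tailed`,
#'     applied to this direction's tail);
#'   \item connected components of suprathreshold voxels;
#'   \item corrected cluster p from the expected cluster count
#'     E[m] = resels x EC density at u, the expected suprathreshold
#'     volume E[N] = S x P(T > u), the extent tail
#'     P(n >= k) = exp(-beta k^(2/3)) with beta matched so the
#'     implied mean extent equals E[N]/E[m], and
#'     p_corr = 1 - exp(-E[m] P(n >= k));
#'   \item retained clusters need p_corr < `cluster_alpha` and extent
#'     strictly greater than `min_extent`.
#' }
#'
#' @param stat a directional `stat_map` (from [slope_difference_map()]).
#' @param smoothness a `smoothness_estimate`.
#' @param cluster_forming_p voxel-level threshold (two-tailed when
#'   `two_tailed`), default 0.01.
#' @param cluster_alpha cluster-level alpha, default 0.05.
#' @param min_extent strict extent bound in voxels, default 100.
#' @param connectivity 6, 18 or 26.
#' @param two_tailed split `cluster_forming_p` across the two tails
#'   (default TRUE).
#' @return object of class `cluster_inference`: `clusters` (retained,
#'   with `corrected_p`), `all_clusters`, `threshold_t`, `expected_m`,
#'   `direction`, thresholds, `smoothness`, `df`.
#' @export
grf_cluster_inference <- function(stat, smoothness, cluster_forming_p = 0.01,
                                  cluster_alpha = 0.05, min_extent = 100L,
                                  connectivity = 18L, two_tailed = TRUE) {
  stopifnot(cluster_forming_p > 0, cluster_forming_p <= 0.05)
  if (smoothness$resels <= 0) stop("non-positive resel count")
  p_tail <- if (two_tailed) cluster_forming_p / 2 else cluster_forming_p
  u <- stats::qt(p_tail, stat$df, lower.tail = FALSE)
  direction <- stat$direction %||% if (stat$tail == "negative") "nc_greater" else "nc_less"
  signed <- if (direction == "nc_greater") -stat$t else stat$t
  supra <- !is.na(signed) & signed > u
  grid <- stat$grid
  Em <- smoothness$resels * ec_density_t_3d(u, stat$df)
  S <- stat$analysis_mask$n_voxels
  EN <- S * stats::pt(u, stat$df, lower.tail = FALSE)
  En <- EN / Em
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  clusters <- label_clusters(mask_volume(grid, supra), connectivity)
  clusters <- lapply(clusters, function(cl) {
    p_ext <- exp(-beta * cl$extent^(2 / 3))
    cl$corrected_p <- 1 - exp(-Em * p_ext)
    cl
  })
  keep <- vapply(clusters, function(cl) {
    cl$corrected_p < cluster_alpha && cl$extent > min_extent
  }, logical(1))
  structure(list(clusters = clusters[keep], all_clusters = clusters,
                 threshold_t = u, expected_m = Em, expected_extent = En,
                 direction = direction, cluster_forming_p = cluster_forming_p,
                 cluster_alpha = cluster_alpha, min_extent = min_extent,
                 smoothness = smoothness, df = stat$df),
            class = "cluster_inference")
}
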