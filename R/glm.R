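#' Gray-matter analysis mask
#'
#' Conventional absolute-threshold GM mask: voxels whose mean modulated GM
#' across the supplied subjects exceeds `threshold`, with constant
#' (zero-variance) voxels removed since no regression is estimable there.
#'
#' @param volumes list of [gm_volume] on one grid.
#' @param threshold absolute mean-GM cutoff (default 0.1).
#' @param exclude optional [mask_volume] of voxels to drop (e.g. the seed's
#'   own voxels when self-covariance is not of interest).
#' @return a [mask_volume].
#' @export
gm_analysis_mask <- function(volumes, threshold = 0.1, exclude = NULL) {
  grid <- volumes[[1]]$grid
  n <- length(volumes)
  s1 <- array(0, grid$shape); s2 <- array(0, grid$shape)
  for (v in volumes) {
    stop_if_grid_mismatch(v$grid, grid, v$subject_id)
    s1 <- s1 + v$data
    s2 <- s2 + v$data^2
  }
  mu <- s1 / n
  varv <- pmax(s2 / n - mu^2, 0)
  keep <- mu > threshold & varv > 1e-12 * pmax(mu^2, 1e-12)
  if (!is.null(exclude)) keep <- keep & !exclude$data
  mask_volume(grid, keep)
}

#' Within-group covariance design matrix
#'
#' Columns `[intercept, seed, age, sex, education, etiv]`, subjects in
#' cohort order. A constant sex column (single-sex group) is dropped with
#' a warning; any other rank deficiency is an error.
#'
#' @param cohort data.frame with columns `subject_id`, `age`, `sex` (0/1),
#'   `education`, `etiv`; one row per subject.
#' @param seed a `seed_table` from [extract_seed_values()] covering every
#'   cohort subject.
#' @return object of class `design_matrix`: list with `matrix` (n x p),
#'   `roles` (named character), `subjects`.
#' @export
build_within_group_design <- function(cohort, seed) {
  req <- c("subject_id", "age", "sex", "education", "etiv")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  sv <- seed$values[cohort$subject_id]
  if (anyNA(sv)) stop("seed values missing for some subjects")
  X <- cbind(intercept = 1, seed = as.numeric(sv), age = cohort$age,
             sex = as.numeric(cohort$sex), education = cohort$education,
             etiv = cohort$etiv)
  roles <- c(intercept = "intercept", seed = "seed", age = "age", sex = "sex",
             education = "education", etiv = "etiv")
  if (anyNA(X)) stop("missing covariate values")
  new_design(X, roles, cohort$subject_id)
}

new_design <- function(X, roles, subjects, allow_drop_constant = "sex") {
  for (cn in allow_drop_constant) {
    if (cn %in% colnames(X) && stats::var(X[, cn]) == 0) {
      warning(sprintf("constant '%s' column dropped from design", cn))
      X <- X[, colnames(X) != cn, drop = FALSE]
      roles <- roles[names(roles) != cn]
    }
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(matrix = X, roles = roles, subjects = subjects),
            class = "design_matrix")
}

#' Dummy-coded interaction design for two groups
#'
#' Columns `[intercept, seed, group, seed_x_group, age, sex, education,
#' etiv]` with the reference group (normal controls) coded 0 and the
#' patient group coded 1. The interaction coefficient is the difference in
#' covariance slope (patient minus reference).
#'
#' @param cohort data.frame restricted to exactly two groups (`group`
#'   column present).
#' @param seed `seed_table` covering all subjects.
#' @param reference label of the reference group, default `"NC"`.
#' @return a `design_matrix`.
#' @export
build_interaction_design <- function(cohort, seed, reference = "NC") {
  groups <- unique(as.character(cohort$group))
  if (length(groups) != 2L)
    stop("interaction design requires exactly two groups, got ",
         length(groups))
  if (!reference %in% groups)
    stop("reference group '", reference, "' absent from cohort")
  dummy <- as.numeric(cohort$group != reference)
  sv <- as.numeric(seed$values[cohort$subject_id])
  if (anyNA(sv)) stop("seed values missing for some subjects")
  X <- cbind(intercept = 1, seed = sv, group = dummy,
             seed_x_group = sv * dummy, age = cohort$age,
             sex = as.numeric(cohort$sex), education = cohort$education,
             etiv = cohort$etiv)
  roles <- c(intercept = "intercept", seed = "seed", group = "group_dummy",
             seed_x_group = "interaction", age = "age", sex = "sex",
             education = "education", etiv = "etiv")
  if (anyNA(X)) stop("missing covariate values")
  new_design(X, roles, cohort$subject_id)
}

#' Mass-univariate ordinary least squares
#'
#' Fits the design to every in-mask voxel by OLS in one pass. Residuals
#' are retained for smoothness estimation.
#'
#' @param design a `design_matrix`; rows must match `volumes` order.
#' @param volumes list of [gm_volume], one per design row.
#' @param analysis_mask a [mask_volume].
#' @return object of class `glm_fit`: `betas` (p x V), `sigma2` (V),
#'   `df`, `residuals` (n x V), `voxel_index` (linear indices of mask
#'   voxels), `design`, `xtx_inv`, `mask`.
#' @export
fit_voxelwise_glm <- function(design, volumes, analysis_mask) {
  X <- design$matrix
  n <- nrow(X); p <- ncol(X)
  if (length(volumes) != n) stop("one volume per design row required")
  if (n <= p) stop("need more subjects than design columns (n > p)")
  grid <- analysis_mask$grid
  idx <- which(analysis_mask$data)
  if (length(idx) == 0L) stop("empty analysis mask")
  Y <- matrix(0, n, length(idx))
  for (i in seq_len(n)) {
    stop_if_grid_mismatch(volumes[[i]]$grid, grid, volumes[[i]]$subject_id)
    Y[i, ] <- volumes[[i]]$data[idx]
  }
  if (!all(is.finite(Y))) stop("non-finite voxel data inside mask")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- n - p
  sigma2 <- colSums(res^2) / df
  structure(list(betas = betas, sigma2 = sigma2, df = df, residuals = res,
                 voxel_index = idx, design = design,
                 xtx_inv = chol2inv(qr.R(qx)), mask = analysis_mask),
            class = "glm_fit")
}

map_from_values <- function(values, idx, grid) {
  a <- array(NA_real_, grid$shape)
  a[idx] <- values
  a
}

#' T contrast over a voxel-wise fit
#'
#' t = c'beta / sqrt(sigma2 c'(X'X)^-1 c), with p-values from Student's t
#' with the residual degrees of freedom, for the requested tail. Voxels
#' whose residual variance is (numerically) zero have no defined t and are
#' dropped from the map's analysis mask with a warning.
#'
#' @param fit a `glm_fit`.
#' @param contrast numeric vector of length p, or the name of a design
#'   column.
#' @param tail `"positive"`, `"negative"` or `"two_sided"`.
#' @return object of class `stat_map`: `t` and `p` (3D arrays, NA outside
#'   mask), `contrast`, `df`, `tail`, `analysis_mask`, `grid`.
#' @export
t_contrast <- function(fit, contrast, tail = c("positive", "negative", "two_sided")) {
  tail <- match.arg(tail)
  X <- fit$design$matrix
  if (is.character(contrast)) {
    cn <- contrast
    contrast <- as.numeric(colnames(X) == cn)
    if (sum(contrast) != 1L) stop("unknown design column: ", cn)
  }
  if (length(contrast) != ncol(X)) stop("contrast length must equal p")
  grid <- fit$mask$grid
  cvar <- drop(t(contrast) %*% fit$xtx_inv %*% contrast)
  scale2 <- fit$sigma2 * cvar
  eff <- drop(contrast %*% fit$betas)
  ok <- scale2 > max(1e-24, 1e-18 * stats::median(scale2[scale2 > 0], na.rm = TRUE))
  if (any(!ok))
    warning(sprintf("%d zero-variance voxels removed from analysis mask",
                    sum(!ok)))
  idx <- fit$voxel_index[ok]
  tval <- eff[ok] / sqrt(scale2[ok])
  pval <- switch(tail,
    positive = stats::pt(tval, fit$df, lower.tail = FALSE),
    negative = stats::pt(tval, fit$df),
    two_sided = 2 * stats::pt(abs(tval), fit$df, lower.tail = FALSE))
  mdat <- array(FALSE, grid$shape)
  mdat[idx] <- TRUE
  mask <- mask_volume(grid, mdat)
  structure(list(t = map_from_values(tval, idx, grid),
                 p = map_from_values(pval, idx, grid),
                 contrast = contrast, df = fit$df, tail = tail,
                 analysis_mask = mask, grid = grid),
            class = "stat_map")
}

#' Benjamini-Hochberg rejection set
#'
#' Classic step-up false-discovery-rate procedure over the in-mask voxel
#' p-values: with ordered p(1) <= ... <= p(m), find the largest k with
#' p(k) <= k q / m and reject p(1..k).
#'
#' @param stat a `stat_map`.
#' @param q FDR level in (0,1), default 0.05.
#' @return a [mask_volume] of significant voxels (possibly empty).
#' @export
fdr_threshold <- function(stat, q = 0.05) {
  stopifnot(q > 0, q < 1)
  idx <- which(stat$analysis_mask$data)
  if (length(idx) == 0L) stop("empty analysis mask")
  p <- stat$p[idx]
  m <- length(p)
  o <- order(p)
  below <- p[o] <= q * seq_len(m) / m
  k <- if (any(below)) max(which(below)) else 0L
  sig <- logical(m)
  if (k > 0L) sig[o[seq_len(k)]] <- TRUE
  data <- array(FALSE, stat$grid$shape)
  data[idx[sig]] <- TRUE
  mask_volume(stat$grid, data)
}

#' Extent-filtered clusters of a significance mask
#'
#' Labels connected components and keeps those with extent strictly
#' greater than `min_voxels` ("larger than" the reporting threshold),
#' in descending extent order.
#'
#' @param mask a [mask_volume].
#' @param min_voxels strict lower extent bound (default 100).
#' @param connectivity 6, 18 or 26 (default 18).
#' @return list of `scn_cluster` objects (possibly empty).
#' @export
extent_filter <- function(mask, min_voxels = 100L, connectivity = 18L) {
  stopifnot(min_voxels >= 1L)
  cl <- label_clusters(mask, connectivity)
  cl[vapply(cl, function(x) x$extent > min_voxels, logical(1))]
}
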