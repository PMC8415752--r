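residualize <- function(v, Z) {
  qz <- qr(Z)
  v - Z %*% qr.coef(qz, v)
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed (with intercept) on the covariates; two-tailed p from
#' t = r sqrt(df / (1 - r^2)) with df = n - n_covariates - 2. With no
#' covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors, one value per subject.
#' @param covariates NULL, a numeric vector, or an n x q matrix /
#'   data.frame of covariates (age, sex, education in the reported
#'   analyses).
#' @return object of class `partial_correlation`: `r`, `p_two_tailed`,
#'   `n`, `n_covariates`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
  } else {
    Z <- cbind(1, as.matrix(covariates))
  }
  if (anyNA(x) || anyNA(y) || anyNA(Z)) stop("missing values not allowed")
  q <- ncol(Z) - 1L
  df <- n - q - 2L
  if (df < 1L) stop("insufficient n for ", q, " covariates")
  rx <- residualize(x, Z); ry <- residualize(y, Z)
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300))
    stop("constant variable after residualization")
  r <- drop(stats::cor(rx, ry))
  r <- max(min(r, 1), -1)
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(r = r, p_two_tailed = min(p, 1), n = n, n_covariates = q,
                 df = df),
            class = "partial_correlation")
}

#' One-way ANOVA with Bonferroni post hoc tests
#'
#' Omnibus F test across groups followed by pairwise pooled-variance
#' t tests with Bonferroni adjustment (raw p times the number of pairs,
#' capped at 1) — the standard demographics table workflow.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level used for the flags, default 0.05.
#' @return list with `anova` (data.frame: F, df1, df2, p) and `pairwise`
#'   (data.frame: group1, group2, p_raw, p_bonferroni, significant).
#' @export
group_anova_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  res <- data.frame(F = tab[1, "F value"], df1 = tab[1, "Df"],
                    df2 = tab[2, "Df"], p = tab[1, "Pr(>F)"])
  pt_raw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
  pairs <- which(!is.na(pt_raw), arr.ind = TRUE)
  m <- nrow(pairs)
  pw <- data.frame(
    group1 = colnames(pt_raw)[pairs[, "col"]],
    group2 = rownames(pt_raw)[pairs[, "row"]],
    p_raw = pt_raw[pairs])
  pw$p_bonferroni <- pmin(1, pw$p_raw * m)
  pw$significant <- pw$p_bonferroni < alpha
  list(anova = res, pairwise = pw)
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction (the table is 2 x k with k > 2);
#' df = (2 - 1)(k - 1).
#'
#' @param table 2 x k matrix of counts (e.g. men/women by group).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- stats::chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("non-positive expected counts")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Power of the fixed-effects (ANCOVA) F test
#'
#' Noncentral-F power with effect size f (Cohen), noncentrality
#' lambda = f^2 N, numerator df (default n_groups - 1) and denominator
#' df = N - n_groups - n_covariates.
#'
#' @param n_total total sample size N.
#' @param effect_size_f Cohen's f.
#' @param n_groups number of groups.
#' @param n_covariates number of covariates.
#' @param alpha type-I level.
#' @param numerator_df override for the numerator df (the reporting of
#'   such calculations is often ambiguous about it, so it is explicit).
#' @return power in (0, 1).
#' @export
ancova_power <- function(n_total, effect_size_f, n_groups = 4L,
                         n_covariates = 0L, alpha = 0.05,
                         numerator_df = NULL) {
  df1 <- numerator_df %||% (n_groups - 1L)
  df2 <- n_total - n_groups - n_covariates
  if (df2 < 1L) stop("denominator df < 1 at N = ", n_total)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = effect_size_f^2 * n_total,
            lower.tail = FALSE)
}

#' Required sample size for the ANCOVA F test
#'
#' Smallest total N whose power reaches `power` under [ancova_power()].
#'
#' @inheritParams ancova_power
#' @param power target power (1 - beta).
#' @return integer N.
#' @export
ancova_required_n <- function(effect_size_f, power = 0.80, n_groups = 4L,
                              n_covariates = 0L, alpha = 0.05,
                              numerator_df = NULL) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1, effect_size_f >= 0)
  if (effect_size_f == 0 && power > alpha)
    stop("power above alpha is unreachable with zero effect size")
  N <- n_groups + n_covariates + 2L
  while (ancova_power(N, effect_size_f, n_groups, n_covariates, alpha,
                      numerator_df) < power) {
    N <- N + 1L
    if (N > 1e6) stop("required N exceeds 1e6")
  }
  N
}
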