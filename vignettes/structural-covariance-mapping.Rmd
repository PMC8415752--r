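---
title: "Mapping gray-matter structural covariance networks: models, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gray-matter structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A structural covariance network (SCN) is the pattern of across-subject
association between the gray-matter (GM) measure of a *seed* region and
the GM measure at every other voxel. `scnmap` works on modulated GM
density volumes — voxel-based-morphometry maps scaled by the Jacobian of
spatial normalization so that values reflect regional volume — all
resident on one common MNI-space grid. The package never resamples: a
grid mismatch (shape or affine beyond 1e-4 mm) is an error, because it
signals heterogeneous preprocessing that silent interpolation would
hide.

Within one group, the covariance map for a seed is the mass-univariate
ordinary-least-squares model at every in-mask voxel $v$:

$$ y_v = \beta_0 + \beta_1 \,\text{seed} + \beta_2\,\text{age} +
\beta_3\,\text{sex} + \beta_4\,\text{education} + \beta_5\,\text{eTIV}
+ \varepsilon_v $$

where "seed" is the subject's mean modulated GM inside the seed mask and
eTIV (estimated total intracranial volume, mm³) absorbs head size. The
map of interest is the one-tailed positive $t$ statistic on $\beta_1$
(negative covariance mapping exists but is off by default). Voxel-level
multiplicity is handled by classic Benjamini–Hochberg FDR (step-up,
independence/PRDS variant — the convention of the standard neuroimaging
packages, not Benjamini–Yekutieli), and surviving voxels are reported as
connected clusters strictly larger than 100 voxels (337.5 mm³ on the
working grid).

Between groups, covariance differences are differences in *slope*. With
the reference group coded 0 and the patient group 1, the joint model
adds `group` and `seed × group` columns; the interaction coefficient is
the patient-minus-reference slope difference, so **negative** interaction
$t$ means the reference group covaries more strongly. Direction
`nc_greater` therefore selects the negative tail, matching the sign
convention of reported peak intensities. Residual variance is pooled
across the two groups by the single joint model (homoscedasticity
assumed).

### Cluster-level random-field-theory correction

The interaction map is thresholded per direction at the per-tail voxel
quantile (two-tailed $p < 0.01$ split as $0.005$ per tail by default;
per-tail $0.01$ is available via `two_tailed = FALSE`). Suprathreshold
components under 18-connectivity receive a corrected $p$ from
stationary RFT for $t$ fields:

* expected cluster count $E[m] = R \cdot \rho_3(u)$, with $R$ the resel
  count and $\rho_3$ the 3-D Euler-characteristic density of a $t$ field
  (`ec_density_t_3d()`; it converges to the Gaussian form
  `ec_density_gaussian_3d()` as df grows);
* expected suprathreshold volume $E[N] = S \cdot P(T > u)$ over the $S$
  mask voxels, giving an expected extent $E[n] = E[N]/E[m]$;
* extent tail $P(n \ge k) = \exp(-\beta k^{2/3})$ with $\beta$ matched
  so the implied mean extent equals $E[n]$
  ($\beta = (\Gamma(5/2)/E[n])^{2/3}$);
* corrected $p = 1 - \exp(-E[m]\,P(n \ge k))$, retained when below the
  cluster $\alpha$ **and** the extent strictly exceeds the 100-voxel
  bound.

Smoothness is *estimated from the residuals of each fitted model*, not
assumed from the applied kernel, because data smoothness exceeds kernel
smoothness. With normalized residuals $e_i(v) = r_i(v)/\sqrt{\sum_i
r_i(v)^2}$, the summed squared forward difference along axis $k$
estimates $2(1-\rho_k)$, the per-step derivative variance of a
unit-variance field; $\mathrm{FWHM}_k = \sqrt{4\ln 2/\lambda_k}$ with
$\lambda_k$ in mm⁻². The finite-difference reading of the Gaussian
autocorrelation biases the FWHM upward by about 2% at 6 mm on a 1.5 mm
grid — well inside the 15% recovery tolerance the validation suite
enforces — so no correction factor is applied. Non-stationary cluster
correction is out of scope.

### Peaks, labels and cognition

Peaks are the cluster voxel of maximal $|t|$ (signed value reported).
When a map has more than one cluster, the peak search is restricted to
the atlas scope, falling back to the whole cluster with label
`"unlabeled"` when the intersection is empty; single-cluster maps report
the global peak unrestricted. Ties break to the lexicographically
smallest voxel index, and clusters order by descending extent with the
same tie-break, so report rows are bit-for-bit reproducible. Mean GM in
a 4-mm sphere around each retained peak is then related to cognitive
scores by partial correlation within the patient group — Pearson
correlation of the residuals after regressing both variables on age,
sex (0/1) and education, with $t = r\sqrt{df/(1-r^2)}$, $df = n -
q - 2$. eTIV is deliberately **not** controlled there, mirroring the
reported covariate set, and the $p < 0.05$ flags are uncorrected across
the many correlations — a reporting convention, not an inferential
claim; treat flagged rows as descriptive.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| working voxel size | 1.5 | mm | 100 voxels = 337.5 mm³ and every reported peak coordinate is a multiple of 1.5; the normalized voxel size is otherwise unstated |
| smoothing FWHM | 6 / 12 | mm | 6 for hippocampal/basal-forebrain seeds, 12 for the network spheres; seed means are taken from the same smoothed maps the voxels come from |
| sphere radius | 4 | mm | seed spheres and peak-extraction spheres |
| GM analysis mask | mean GM > 0.1 | density | conventional absolute-threshold heuristic; constant voxels are removed (no regression is estimable); configurable |
| FDR q | 0.05 | — | voxel-level, one-tailed positive |
| cluster-forming p | 0.01 two-tailed | — | split 0.005 per tail across the two directional maps |
| cluster alpha | 0.05 | — | per directional map |
| extent rule | > 100 | voxels | strict inequality ("larger than") |
| connectivity | 18 | — | faces+edges, the cluster convention of the reference software; 6/26 available |

## The synthetic-data generator

`scn_scenario()` + `generate_gm_volumes()` emulate exactly the
statistical structure the analysis assumes: a latent seed value $s_i
\sim N(0.5, 0.1)$ per subject; effect-region voxels equal to baseline
(0.5) plus $\text{slope}_g\,(s_i - \mu_s)$ plus a small age effect
(−0.002 density/year, centred at 65 y, so the covariate-adjustment path
is exercised) plus Gaussian noise (white, SD 0.1, smoothed to 6-mm
FWHM) inside a brain mask kept clear of the grid edge (so the noise
field is stationary within the mask despite the zero-padding boundary).
Seed-region voxels are overwritten with $s_i$ itself **after** the
noise is laid down: the honest mask→mean extraction path then recovers
the latent value exactly, and every non-seed voxel is independent of
the measured seed under a null scenario — which makes the type-I-error
simulations exact rather than approximate. The seed's own voxels are
excluded from the analysis mask (their covariance with the seed is
trivially perfect).

Cohorts draw demographics and cognitive scores per group from normal
distributions with the reference moments (four groups of 42/35/43/41),
clipped to instrument ranges (MoCA 0–30, AVLT recall 0–15, recognition
0–24, age 40–95 y); clipping was chosen over rejection sampling because
winsorizing perturbs the mean far less than discarding an upper tail.
CDR is set by group; a rule-based classifier (`classify_diagnosis()`)
reproduces the diagnostic logic: education-adjusted MoCA normality
thresholds (19 for ≤ 6 y, 22 for 7–12 y, 24 above — strict lower
bounds), memory-test abnormality as *strictly below* the NC mean minus
1 SD (SCD: exactly one abnormal test, CDR 0, normal MoCA) or minus
1.5 SD (aMCI: CDR 0.5, MoCA at or below threshold), CDR ≥ 1 for AD, and
exclusion for HAMD > 24 or Hachinski > 4 (the boundary values remain
eligible).

What the generator does **not** emulate: cortical anatomy or atrophy
topography, scanner noise and artefacts, non-stationary smoothness,
non-Gaussian GM distributions, and registration error. Passing tests
therefore demonstrate that the estimator and the inference are correct
*under the model's own assumptions* — they do not certify behaviour on
real data where those assumptions bend.

## Numerical choices

* **Voxel indices are 1-based** in the public API (R array convention);
  the affine maps `index − 1`, so NIfTI affines keep their stored
  meaning. A 0-based surface in a 1-based language invites off-by-one
  errors at every array access.
* Smoothing uses a separable truncated-Gaussian kernel (radius 4σ,
  renormalized) with zero boundary — GM maps are zero outside the head —
  so interior mass is conserved; a constant volume is unchanged only
  away from the grid edge.
* Sphere membership uses voxel centres (no partial volumes); Y-band
  bounds are inclusive at both ends; the centre voxel of a sphere is
  always included, so seed masks are never empty.
* Zero-residual-variance voxels (possible in noiseless simulations and
  at injected seed voxels) are dropped from the statistic map's mask
  with a warning rather than yielding infinite $t$.
* A constant sex column (single-sex group) is dropped with a warning;
  any other rank deficiency is an error.
* The Gaussian-limit check of the $t$ EC density is evaluated at
  $u = \Phi^{-1}(0.99)$: the relative error of the limit grows like
  $u^4/(4\,\mathrm{df})$, so a fixed 1% agreement bound is a statement
  about the threshold region the cluster-forming step actually uses,
  not about arbitrary $u$.
* The ANCOVA power calculator takes the numerator df explicitly
  (default `n_groups − 1`, denominator `N − n_groups − n_covariates`,
  noncentrality $f^2 N$), because published G*Power configurations are
  often ambiguous about the test variant; the printed configuration it
  is usually run with does not pin a unique numerator df.

## Validation suite and problem sizes

The acceptance studies run on a 48³ grid at 1.5 mm: slope-difference
recovery with 40 subjects/group, slopes 0.8 vs 0.3, noise SD 0.1 at
6-mm FWHM, 50 replicates (the suite requires the mean interaction
estimate within 10% of the true −0.5); null calibration with 20
subjects/group and 200 replicates (the family-wise rate of the full
two-direction cluster procedure and the BH any-rejection rate must stay
within two binomial standard errors of 0.05); and smoothness recovery
from 40 residual images of known 6-mm noise (within 15% per axis).
These sizes are the package's chosen validation conditions: large
enough for stable rates and smoothness estimation, small enough to run
in minutes.

## Known limitations

Stationary RFT with the 3-D EC term only (no boundary/lower-dimensional
resel terms); no permutation or TFCE inference; no F-tests across more
than two groups in one model (each patient group is compared with the
reference pairwise); no probabilistic atlases, surface seeds or
partial-volume weighting; preprocessing (segmentation, normalization,
modulation) is consumed, never computed.
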