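#' Synthetic test atlas
#'
#' A small label volume with the region kinds the seed registry needs:
#' left/right "hippocampus" boxes spanning the anterior and posterior
#' Y bands, and two small "basal forebrain" compartments. Entirely
#' synthetic geometry for testing and simulation — not anatomy.
#'
#' @param grid a [volume_grid].
#' @return atlas list (`labels`, `grid`, `lookup`) as from [read_atlas()].
#' @export
synthetic_atlas <- function(grid = mni_grid()) {
  mm <- voxel_center_coords(grid)
  lab <- integer(nrow(mm))
  inbox <- function(xr, yr, zr) {
    mm[, 1] >= xr[1] & mm[, 1] <= xr[2] &
    mm[, 2] >= yr[1] & mm[, 2] <= yr[2] &
    mm[, 3] >= zr[1] & mm[, 3] <= zr[2]
  }
  lab[inbox(c(-30, -9), c(-36, 0), c(-15, 6))] <- 4101L   # L hippocampus box
  lab[inbox(c(9, 30), c(-36, 0), c(-15, 6))] <- 4201L     # R hippocampus box
  lab[inbox(c(-6, 6), c(3, 9), c(-12, -3))] <- 9001L      # Ch4p box
  lab[inbox(c(-4.5, 4.5), c(12, 18), c(-12, -3))] <- 9002L # Ch1/2 box
  list(labels = array(lab, grid$shape), grid = grid,
       lookup = data.frame(
         label_id = c(4101L, 4201L, 9001L, 9002L),
         label_name = c("Hippocampus_L", "Hippocampus_R", "Ch4p", "Ch1_2"),
         stringsAsFactors = FALSE))
}

#' Analysis configuration
#'
#' Bundles every threshold of the pipeline: voxel-level FDR q for the
#' within-group maps (0.05), two-tailed cluster-forming p (0.01) and
#' cluster-level alpha (0.05) for the between-group maps, the strict
#' 100-voxel extent rule, cluster connectivity, the GM analysis-mask
#' threshold, the reference group and the RNG seed.
#'
#' @param fdr_q within-group FDR level.
#' @param cluster_forming_p two-tailed voxel-level threshold.
#' @param cluster_alpha cluster-level alpha.
#' @param min_extent strict extent bound (voxels).
#' @param connectivity 6, 18 or 26.
#' @param gm_threshold GM analysis-mask mean threshold.
#' @param reference reference group label.
#' @param rng_seed integer seed.
#' @param output_dir optional directory; when set, run functions write
#'   TSV tables, NIfTI maps and a JSON manifest there.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(fdr_q = 0.05, cluster_forming_p = 0.01,
                            cluster_alpha = 0.05, min_extent = 100L,
                            connectivity = 18L, gm_threshold = 0.1,
                            reference = "NC", rng_seed = 1L,
                            output_dir = NULL) {
  stopifnot(fdr_q > 0, fdr_q < 1, cluster_forming_p > 0,
            cluster_forming_p < 1, cluster_alpha > 0, cluster_alpha < 1,
            min_extent >= 1L)
  structure(list(fdr_q = fdr_q, cluster_forming_p = cluster_forming_p,
                 cluster_alpha = cluster_alpha,
                 min_extent = as.integer(min_extent),
                 connectivity = as.integer(connectivity),
                 gm_threshold = gm_threshold, reference = reference,
                 rng_seed = as.integer(rng_seed), output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration (plus input paths) from YAML
#'
#' Threshold fields feed [analysis_config()]; the remaining fields
#' (`cohort`, `volume_dir`, `atlas_nifti`, `atlas_lookup`, `seeds`,
#' `output_dir`) are file paths used by [run_scn_pipeline()].
#'
#' @param path YAML file.
#' @return list with `config` ([analysis_config]) and `paths`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- analysis_config(
    fdr_q = raw$fdr_q %||% 0.05,
    cluster_forming_p = raw$cluster_forming_p %||% 0.01,
    cluster_alpha = raw$cluster_alpha %||% 0.05,
    min_extent = raw$min_extent %||% 100L,
    connectivity = raw$connectivity %||% 18L,
    gm_threshold = raw$gm_threshold %||% 0.1,
    reference = raw$reference %||% "NC",
    rng_seed = raw$rng_seed %||% 1L,
    output_dir = raw$output_dir)
  paths <- raw[intersect(names(raw),
                         c("cohort", "volume_dir", "atlas_nifti",
                           "atlas_lookup", "seeds", "output_dir"))]
  list(config = cfg, paths = paths)
}

#' Load a cohort table
#' @param path TSV with the required cohort columns.
#' @return data.frame.
#' @export
load_cohort <- function(path) {
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex", "education", "etiv")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  cohort
}

#' Load per-subject GM volumes from a directory
#'
#' Expects `<subject_id>.nii` or `<subject_id>.nii.gz` for every cohort
#' subject; all files must share one grid.
#'
#' @param dir directory of NIfTI files.
#' @param subject_ids character vector.
#' @return named list of [gm_volume].
#' @export
load_volumes <- function(dir, subject_ids) {
  grid <- NULL
  vols <- lapply(subject_ids, function(id) {
    p <- file.path(dir, paste0(id, ".nii"))
    if (!file.exists(p)) p <- paste0(p, ".gz")
    if (!file.exists(p)) stop("missing volume for subject ", id)
    v <- read_gm_volume(p, expected_grid = grid, subject_id = id)
    grid <<- v$grid
    v
  })
  stats::setNames(vols, subject_ids)
}

fwhm_key <- function(f) if (is.na(f)) "raw" else as.character(f)

smooth_cache <- function(volumes, fwhms) {
  out <- list()
  for (f in unique(fwhms)) {
    out[[fwhm_key(f)]] <- if (is.na(f)) volumes else
      lapply(volumes, smooth_gaussian, fwhm_mm = f)
  }
  out
}

atlas_scope_mask <- function(atlas, grid) {
  if (is.null(atlas)) return(NULL)
  mask_volume(grid, array(atlas$labels > 0L, grid$shape))
}

locate_all_peaks <- function(stat, clusters, atlas, grid) {
  scope <- if (length(clusters) > 1L) atlas_scope_mask(atlas, grid) else NULL
  lapply(clusters, locate_peak, stat = stat, atlas = atlas,
         atlas_scope = scope)
}

write_table_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, output_dir, extra = list()) {
  manifest <- c(list(package = "scnmap",
                     version = as.character(utils::packageVersion("scnmap")),
                     config = unclass(config)), extra)
  manifest$config$output_dir <- NULL
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Within-group structural covariance maps
#'
#' For every group and seed: smooth the volumes at the seed's FWHM,
#' extract seed values, regress every in-mask voxel on
#' [intercept, seed, age, sex, education, eTIV], form the positive-tail
#' seed contrast, apply voxel-level Benjamini-Hochberg correction at
#' `fdr_q`, and keep clusters strictly larger than `min_extent` voxels.
#'
#' @param cohort cohort data.frame.
#' @param volumes named list of unsmoothed [gm_volume] (all subjects).
#' @param seeds named list of [seed_spec].
#' @param atlas optional atlas list for peak naming.
#' @param config an [analysis_config()].
#' @return list: `table` (all cluster rows), `results` (per group x seed:
#'   stat map, significance mask, clusters).
#' @export
run_within_group <- function(cohort, volumes, seeds, atlas = NULL,
                             config = analysis_config()) {
  grid <- volumes[[1]]$grid
  cache <- smooth_cache(volumes, vapply(seeds, `[[`, 0, "smoothing_fwhm_mm"))
  groups <- unique(cohort$group)
  results <- list()
  tables <- list()
  for (s in seeds) {
    sm <- cache[[fwhm_key(s$smoothing_fwhm_mm)]]
    mask_s <- build_seed_mask(s, grid, atlas)
    for (g in groups) {
      cg <- cohort[cohort$group == g, , drop = FALSE]
      vols <- sm[cg$subject_id]
      seedtab <- extract_seed_values(vols, mask_s, s$name)
      design <- build_within_group_design(cg, seedtab)
      amask <- gm_analysis_mask(vols, config$gm_threshold, exclude = mask_s)
      fit <- fit_voxelwise_glm(design, vols, amask)
      stat <- t_contrast(fit, "seed", "positive")
      sig <- fdr_threshold(stat, config$fdr_q)
      clusters <- extent_filter(sig, config$min_extent, config$connectivity)
      clusters <- locate_all_peaks(stat, clusters, atlas, grid)
      tab <- cluster_table(clusters, seed = s$name,
                           contrast = paste0(g, " positive"))
      tab$group <- if (nrow(tab)) g else character(0)
      key <- paste(s$name, g, sep = " | ")
      results[[key]] <- list(stat = stat, significant = sig,
                             clusters = clusters, n = nrow(cg), df = fit$df)
      tables[[key]] <- tab
    }
  }
  table <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  if (!is.null(config$output_dir)) {
    write_table_tsv(table, file.path(config$output_dir, "within_group_clusters.tsv"))
    write_manifest(config, config$output_dir,
                   list(step = "within", n_seeds = length(seeds)))
  }
  list(table = table, results = results)
}

#' Between-group slope-difference maps
#'
#' For every patient group (versus the reference) and seed: fit the
#' dummy-coded interaction model on the pooled two-group cohort, map the
#' interaction t in both directions, estimate the residual smoothness,
#' and apply random-field-theory cluster-level correction at the
#' configured thresholds. Contrast labels follow the reporting
#' convention: `"NC > g"` rows carry negative peak intensities.
#'
#' @inheritParams run_within_group
#' @return list: `table` (all retained cluster rows with corrected p),
#'   `results` (per group x seed x direction: `cluster_inference`, stat).
#' @export
run_between_group <- function(cohort, volumes, seeds, atlas = NULL,
                              config = analysis_config()) {
  grid <- volumes[[1]]$grid
  ref <- config$reference
  if (!ref %in% cohort$group) stop("reference group absent: ", ref)
  patient_groups <- setdiff(unique(cohort$group), ref)
  cache <- smooth_cache(volumes, vapply(seeds, `[[`, 0, "smoothing_fwhm_mm"))
  results <- list()
  tables <- list()
  for (s in seeds) {
    sm <- cache[[fwhm_key(s$smoothing_fwhm_mm)]]
    mask_s <- build_seed_mask(s, grid, atlas)
    for (g in patient_groups) {
      cg <- cohort[cohort$group %in% c(ref, g), , drop = FALSE]
      vols <- sm[cg$subject_id]
      seedtab <- extract_seed_values(vols, mask_s, s$name)
      design <- build_interaction_design(cg, seedtab, reference = ref)
      amask <- gm_analysis_mask(vols, config$gm_threshold, exclude = mask_s)
      fit <- fit_voxelwise_glm(design, vols, amask)
      smoothness <- estimate_smoothness(fit)
      for (direction in c("nc_greater", "nc_less")) {
        stat <- slope_difference_map(fit, direction)
        inf <- grf_cluster_inference(stat, smoothness,
                                     config$cluster_forming_p,
                                     config$cluster_alpha,
                                     config$min_extent,
                                     config$connectivity)
        clusters <- locate_all_peaks(stat, inf$clusters, atlas, grid)
        lab <- if (direction == "nc_greater") paste(ref, ">", g)
               else paste(ref, "<", g)
        tab <- cluster_table(clusters, seed = s$name, contrast = lab)
        tab$group <- if (nrow(tab)) g else character(0)
        tab$direction <- if (nrow(tab)) direction else character(0)
        key <- paste(s$name, g, direction, sep = " | ")
        results[[key]] <- list(inference = inf, stat = stat,
                               smoothness = smoothness, df = fit$df,
                               n = nrow(cg))
        tables[[key]] <- tab
      }
    }
  }
  table <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  if (!is.null(config$output_dir)) {
    write_table_tsv(table, file.path(config$output_dir, "between_group_clusters.tsv"))
    write_manifest(config, config$output_dir,
                   list(step = "between", n_seeds = length(seeds)))
  }
  list(table = table, results = results)
}

#' Peak-volume / cognition partial correlations
#'
#' For every retained between-group cluster: extract mean GM in a 4-mm
#' sphere around the peak (from maps smoothed at the originating seed's
#' FWHM) and correlate it with each cognitive score within the patient
#' group, controlling age, sex and education. Rows are flagged at
#' two-tailed p < 0.05, uncorrected, mirroring the reporting convention.
#'
#' @param cohort cohort data.frame including the score columns.
#' @param volumes named list of unsmoothed [gm_volume].
#' @param peak_table the `table` from [run_between_group()].
#' @param seeds seed registry (for the smoothing FWHM of each row's seed).
#' @param scores score column names.
#' @param config an [analysis_config()].
#' @return data.frame: seed, contrast, group, score, r, p, n, flagged.
#' @export
run_correlations <- function(cohort, volumes, peak_table, seeds,
                             scores = c("moca", "avlt_immediate",
                                        "avlt_delayed", "avlt_recognition"),
                             config = analysis_config()) {
  if (nrow(peak_table) == 0L)
    return(data.frame(seed = character(), contrast = character(),
                      group = character(), score = character(),
                      r = numeric(), p = numeric(), n = integer(),
                      flagged = logical()))
  cache <- smooth_cache(volumes, vapply(seeds, `[[`, 0, "smoothing_fwhm_mm"))
  rows <- list()
  for (i in seq_len(nrow(peak_table))) {
    row <- peak_table[i, ]
    s <- seeds[[row$seed]]
    sm <- cache[[fwhm_key(s$smoothing_fwhm_mm)]]
    cg <- cohort[cohort$group == row$group, , drop = FALSE]
    pv <- extract_peak_sphere_volumes(sm[cg$subject_id],
                                      c(row$x, row$y, row$z))
    covs <- cbind(age = cg$age, sex = as.numeric(cg$sex),
                  education = cg$education)
    for (sc in scores) {
      pc <- partial_correlation(pv$values[cg$subject_id], cg[[sc]], covs)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = row$seed, contrast = row$contrast, group = row$group,
        score = sc, r = pc$r, p = pc$p_two_tailed, n = pc$n,
        flagged = pc$p_two_tailed < 0.05)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(config$output_dir))
    write_table_tsv(out, file.path(config$output_dir, "peak_correlations.tsv"))
  out
}

#' Simulate a cohort + volumes to disk
#'
#' Writes `<output_dir>/cohort.tsv`, one NIfTI per subject under
#' `<output_dir>/volumes/`, and `truth.json` with the latent seed values
#' and generating slopes.
#'
#' @param scenario an [scn_scenario].
#' @param output_dir directory to create.
#' @param rng_seed integer seed (cohort and volumes).
#' @return the cohort data.frame, invisibly.
#' @export
simulate_to_dir <- function(scenario, output_dir, rng_seed = 1L) {
  cohort <- generate_cohort(scenario$group_sizes, rng_seed)
  gen <- generate_gm_volumes(scenario, cohort, rng_seed + 1L)
  vdir <- file.path(output_dir, "volumes")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(cohort, file.path(output_dir, "cohort.tsv"))
  for (v in gen$volumes)
    write_volume(v, file.path(vdir, paste0(v$subject_id, ".nii.gz")))
  jsonlite::write_json(
    list(latent = as.list(gen$truth$latent),
         slopes = gen$truth$slopes,
         noise_sd = scenario$noise_sd,
         noise_fwhm_mm = scenario$noise_fwhm_mm),
    file.path(output_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Run the full pipeline from a YAML configuration
#'
#' File-based front end used by the `scn` command-line script: loads the
#' cohort, volumes, atlas and seed registry named in the configuration
#' and runs the requested steps.
#'
#' @param config_path YAML file (see [read_analysis_config()]).
#' @param steps subset of `c("within", "between", "correlate")`.
#' @return list with the step outputs.
#' @export
run_scn_pipeline <- function(config_path,
                             steps = c("within", "between", "correlate")) {
  cc <- read_analysis_config(config_path)
  config <- cc$config
  paths <- cc$paths
  cohort <- load_cohort(paths$cohort)
  volumes <- load_volumes(paths$volume_dir, cohort$subject_id)
  atlas <- if (!is.null(paths$atlas_nifti))
    read_atlas(paths$atlas_nifti, paths$atlas_lookup,
               expected_grid = volumes[[1]]$grid)
  seeds <- read_seed_registry(paths$seeds)
  out <- list()
  if ("within" %in% steps)
    out$within <- run_within_group(cohort, volumes, seeds, atlas, config)
  if ("between" %in% steps)
    out$between <- run_between_group(cohort, volumes, seeds, atlas, config)
  if ("correlate" %in% steps) {
    if (is.null(out$between))
      out$between <- run_between_group(cohort, volumes, seeds, atlas, config)
    out$correlations <- run_correlations(cohort, volumes,
                                         out$between$table, seeds,
                                         config = config)
  }
  out
}
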