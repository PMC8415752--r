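#' Seed-region specification
#'
#' A seed is one of three kinds: a sphere around an MNI coordinate, an
#' atlas-label region restricted to an MNI Y band (used for the anterior /
#' posterior hippocampus along its long axis), or a plain atlas-label
#' region (used for the cholinergic basal-forebrain compartments). Each
#' seed carries the smoothing FWHM applied to the whole-brain maps it is
#' analysed on: 12 mm for the large-scale-network spheres, 6 mm for the
#' hippocampal and basal-forebrain seeds.
#'
#' @param name seed name.
#' @param kind one of `"sphere"`, `"coordinate_band"`, `"atlas_labels"`.
#' @param center_mni numeric(3), sphere centre in MNI mm (sphere only).
#' @param radius_mm sphere radius in mm (sphere only; default 4).
#' @param atlas_labels integer label ids (band / labels kinds).
#' @param y_range_mm numeric(2) inclusive MNI-Y range, ascending (band only).
#' @param smoothing_fwhm_mm FWHM (mm) of the maps this seed is analysed on.
#' @return object of class `seed_spec`.
#' @export
seed_spec <- function(name, kind, center_mni = NULL, radius_mm = NULL,
                      atlas_labels = NULL, y_range_mm = NULL,
                      smoothing_fwhm_mm = NA_real_) {
  kind <- match.arg(kind, c("sphere", "coordinate_band", "atlas_labels"))
  if (kind == "sphere") {
    stopifnot(length(center_mni) == 3L)
    if (is.null(radius_mm)) radius_mm <- 4
    stopifnot(radius_mm > 0)
    if (!is.null(atlas_labels) || !is.null(y_range_mm))
      stop("sphere seeds take only center_mni and radius_mm")
  } else {
    if (!is.null(center_mni) || !is.null(radius_mm))
      stop("atlas seeds take no center/radius")
    stopifnot(length(atlas_labels) >= 1L)
    if (kind == "coordinate_band") {
      stopifnot(length(y_range_mm) == 2L, y_range_mm[1] < y_range_mm[2])
    } else if (!is.null(y_range_mm)) {
      stop("y_range_mm only applies to coordinate_band seeds")
    }
  }
  structure(list(name = name, kind = kind,
                 center_mni = if (!is.null(center_mni)) as.numeric(center_mni),
                 radius_mm = radius_mm,
                 atlas_labels = if (!is.null(atlas_labels)) as.integer(atlas_labels),
                 y_range_mm = if (!is.null(y_range_mm)) as.numeric(y_range_mm),
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "seed_spec")
}

#' Mirror a sphere seed across the midline
#'
#' Returns the contralateral seed, obtained by negating the MNI x
#' coordinate of the sphere centre. Only sphere seeds can be mirrored;
#' atlas-defined regions have explicit left/right labels instead.
#'
#' @param spec a sphere [seed_spec].
#' @return the mirrored [seed_spec], named `"mirror <name>"`.
#' @export
mirror_seed <- function(spec) {
  if (spec$kind != "sphere") stop("only sphere seeds can be mirrored")
  out <- spec
  out$center_mni[1] <- -out$center_mni[1]
  out$name <- if (startsWith(spec$name, "mirror ")) {
    sub("^mirror ", "", spec$name)
  } else {
    paste("mirror", spec$name)
  }
  out
}

#' The default ten-seed registry
#'
#' Four 4-mm spheres anchoring large-scale networks (right entorhinal
#' cortex 25,-9,-28; left posterior cingulate -2,-36,35; right
#' frontoinsular cortex 38,26,-10; right dorsolateral prefrontal cortex
#' 44,36,20; all analysed on 12-mm-smoothed maps), four hippocampal
#' long-axis bands (anterior Y in [-18,-2], posterior Y in [-24..-42]
#' i.e. [-42,-24] ascending, left and right; 6-mm maps) and the two
#' basal-forebrain compartments Ch4p and Ch1/2 (6-mm maps).
#'
#' Label ids follow the supplied atlas lookup; the defaults match the
#' packaged synthetic atlas (see [synthetic_atlas()]).
#'
#' @param hippocampus_labels named integer(2): left and right hippocampus.
#' @param ch4p_labels,ch12_labels basal-forebrain label ids.
#' @return named list of [seed_spec] objects, length 10.
#' @export
default_seed_registry <- function(hippocampus_labels = c(left = 4101L, right = 4201L),
                                  ch4p_labels = 9001L, ch12_labels = 9002L) {
  seeds <- list(
    seed_spec("R EC", "sphere", center_mni = c(25, -9, -28),
              smoothing_fwhm_mm = 12),
    seed_spec("L PCC", "sphere", center_mni = c(-2, -36, 35),
              smoothing_fwhm_mm = 12),
    seed_spec("R FIC", "sphere", center_mni = c(38, 26, -10),
              smoothing_fwhm_mm = 12),
    seed_spec("R DLPFC", "sphere", center_mni = c(44, 36, 20),
              smoothing_fwhm_mm = 12),
    seed_spec("L anterior hippocampus", "coordinate_band",
              atlas_labels = hippocampus_labels[["left"]],
              y_range_mm = c(-18, -2), smoothing_fwhm_mm = 6),
    seed_spec("R anterior hippocampus", "coordinate_band",
              atlas_labels = hippocampus_labels[["right"]],
              y_range_mm = c(-18, -2), smoothing_fwhm_mm = 6),
    seed_spec("L posterior hippocampus", "coordinate_band",
              atlas_labels = hippocampus_labels[["left"]],
              y_range_mm = c(-42, -24), smoothing_fwhm_mm = 6),
    seed_spec("R posterior hippocampus", "coordinate_band",
              atlas_labels = hippocampus_labels[["right"]],
              y_range_mm = c(-42, -24), smoothing_fwhm_mm = 6),
    seed_spec("Ch4p", "atlas_labels", atlas_labels = ch4p_labels,
              smoothing_fwhm_mm = 6),
    seed_spec("Ch1/2", "atlas_labels", atlas_labels = ch12_labels,
              smoothing_fwhm_mm = 6)
  )
  names(seeds) <- vapply(seeds, `[[`, "", "name")
  seeds
}

#' Read a seed registry from YAML
#'
#' The file holds a list of entries with fields `name`, `kind` and the
#' kind's parameters, mirroring [seed_spec()].
#' @param path YAML file.
#' @return named list of [seed_spec].
#' @export
read_seed_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  seeds <- lapply(raw, function(e) {
    seed_spec(e$name, e$kind,
              center_mni = e$center_mni,
              radius_mm = e$radius_mm,
              atlas_labels = unlist(e$atlas_labels),
              y_range_mm = unlist(e$y_range_mm),
              smoothing_fwhm_mm = e$smoothing_fwhm_mm %||% NA_real_)
  })
  names(seeds) <- vapply(seeds, `[[`, "", "name")
  seeds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an atlas label volume with its lookup table
#'
#' @param nifti_path label volume (integer codes) on the analysis grid.
#' @param lookup_path TSV with columns `label_id`, `label_name`.
#' @param expected_grid optional grid the atlas must match.
#' @return list with `labels` (integer 3D array), `grid`, `lookup`
#'   (data.frame).
#' @export
read_atlas <- function(nifti_path, lookup_path, expected_grid = NULL) {
  img <- RNifti::readNifti(nifti_path)
  grid <- grid_from_nifti(img)
  if (!is.null(expected_grid)) stop_if_grid_mismatch(grid, expected_grid, "atlas")
  lookup <- utils::read.delim(lookup_path, stringsAsFactors = FALSE)
  stopifnot(all(c("label_id", "label_name") %in% names(lookup)))
  list(labels = array(as.integer(round(img)), dim = dim(img)[1:3]),
       grid = grid, lookup = lookup)
}

voxel_center_coords <- function(grid) {
  ijk <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                               j = seq_len(grid$shape[2]),
                               k = seq_len(grid$shape[3])))
  voxel_to_mni(grid, ijk)
}

#' Sphere mask around an MNI coordinate
#'
#' Includes every voxel whose centre lies within `radius_mm` (Euclidean,
#' mm) of `center_mni`; the voxel containing the centre is always
#' included, so the mask is never empty.
#'
#' @param center_mni numeric(3) MNI mm.
#' @param radius_mm positive radius in mm.
#' @param grid a [volume_grid].
#' @return a [mask_volume].
#' @export
build_sphere_mask <- function(center_mni, radius_mm, grid) {
  stopifnot(radius_mm > 0)
  cv <- mni_to_voxel(grid, center_mni)  # errors if out of bounds
  # bounding box in voxels, generous to anisotropic grids
  half <- ceiling(radius_mm / grid$voxel_size_mm) + 1L
  lo <- pmax(cv - half, 1L)
  hi <- pmin(cv + half, grid$shape)
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- voxel_to_mni(grid, ijk)
  d2 <- rowSums(sweep(mm, 2, center_mni)^2)
  sel <- ijk[d2 <= radius_mm^2, , drop = FALSE]
  data <- array(FALSE, dim = grid$shape)
  if (nrow(sel) > 0) data[sel] <- TRUE
  data[cv[1], cv[2], cv[3]] <- TRUE
  mask_volume(grid, data)
}

#' Atlas-label mask
#'
#' @param atlas atlas list from [read_atlas()] (or any list with `labels`
#'   and `grid`).
#' @param labels integer label ids to include; all must occur in the atlas.
#' @param grid analysis grid the atlas must match.
#' @return a [mask_volume].
#' @export
build_label_mask <- function(atlas, labels, grid) {
  stop_if_grid_mismatch(atlas$grid, grid, "atlas")
  labels <- as.integer(labels)
  present <- labels %in% atlas$labels
  if (!all(present))
    stop("label ids not found in atlas: ", paste(labels[!present], collapse = ", "))
  mask_volume(grid, array(atlas$labels %in% labels, dim = grid$shape))
}

#' Atlas-label mask restricted to an MNI Y band
#'
#' Selects voxels whose atlas label is in `labels` and whose MNI y
#' coordinate lies in the closed interval `y_range_mm`. Used to split the
#' hippocampus along its long axis (anterior band Y in [-18, -2],
#' posterior band Y in [-42, -24]).
#'
#' @inheritParams build_label_mask
#' @param y_range_mm numeric(2) ascending, inclusive at both ends.
#' @return a [mask_volume]; empty results are an error (wrong labels or band).
#' @export
build_coordinate_band_mask <- function(atlas, labels, y_range_mm, grid) {
  stopifnot(length(y_range_mm) == 2L, y_range_mm[1] < y_range_mm[2])
  base <- build_label_mask(atlas, labels, grid)
  mm <- voxel_center_coords(grid)
  yok <- array(mm[, 2] >= y_range_mm[1] & mm[, 2] <= y_range_mm[2],
               dim = grid$shape)
  data <- base$data & yok
  if (!any(data))
    stop("empty band mask: no atlas voxels with Y in [",
         y_range_mm[1], ", ", y_range_mm[2], "] mm")
  mask_volume(grid, data)
}

#' Build the mask for any seed specification
#'
#' @param spec a [seed_spec].
#' @param grid analysis grid.
#' @param atlas atlas list (required for atlas-based kinds).
#' @return a [mask_volume].
#' @export
build_seed_mask <- function(spec, grid, atlas = NULL) {
  switch(spec$kind,
    sphere = build_sphere_mask(spec$center_mni, spec$radius_mm, grid),
    coordinate_band = {
      if (is.null(atlas)) stop("atlas required for seed ", spec$name)
      build_coordinate_band_mask(atlas, spec$atlas_labels, spec$y_range_mm, grid)
    },
    atlas_labels = {
      if (is.null(atlas)) stop("atlas required for seed ", spec$name)
      build_label_mask(atlas, spec$atlas_labels, grid)
    })
}

#' Per-subject mean GM within a seed mask
#'
#' The seed value of a subject is the arithmetic mean of the modulated GM
#' density over the mask voxels; these values are the covariate of
#' interest in all covariance models.
#'
#' @param volumes list of [gm_volume], all on the mask's grid.
#' @param mask a [mask_volume] with at least one voxel.
#' @param seed_name name stored on the result.
#' @return object of class `seed_table`: list with `seed_name` and
#'   `values` (named numeric, one per subject).
#' @export
extract_seed_values <- function(volumes, mask, seed_name = "seed") {
  if (mask$n_voxels < 1L) stop("empty seed mask")
  vals <- vapply(volumes, function(v) {
    stop_if_grid_mismatch(v$grid, mask$grid, v$subject_id)
    mean(v$data[mask$data])
  }, numeric(1))
  names(vals) <- vapply(volumes, `[[`, "", "subject_id")
  if (anyDuplicated(names(vals))) stop("duplicated subject ids")
  structure(list(seed_name = seed_name, values = vals), class = "seed_table")
}
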