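neighbour_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g <- g[keep, , drop = FALSE]
  # half set: one offset per unordered voxel pair
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
    drop = FALSE]
}

# lexicographic order on (i, j, k) rows
lex_order <- function(ijk) order(ijk[, 1], ijk[, 2], ijk[, 3])

new_cluster <- function(lin_idx, grid) {
  ijk <- arrayInd(lin_idx, grid$shape)
  o <- lex_order(ijk)
  structure(list(voxel_indices = lin_idx[o], ijk = ijk[o, , drop = FALSE],
                 extent = length(lin_idx),
                 extent_mm3 = length(lin_idx) * prod(grid$voxel_size_mm),
                 grid = grid, peak_mni = NULL, peak_intensity = NULL,
                 peak_label = NULL, corrected_p = NULL),
            class = "scn_cluster")
}

#' Connected components of a binary mask
#'
#' Labels maximal connected components under face (6), face+edge (18) or
#' face+edge+corner (26) adjacency, via the voxel-adjacency graph.
#' Ordering is deterministic: descending extent, ties broken by the
#' lexicographically smallest member voxel index.
#'
#' @param mask a [mask_volume].
#' @param connectivity 6, 18 or 26 (default 18, the convention of the
#'   standard neuroimaging cluster tools).
#' @return list of `scn_cluster` objects; empty list for an empty mask.
#' @export
label_clusters <- function(mask, connectivity = 18L) {
  grid <- mask$grid
  idx <- which(mask$data)
  n <- length(idx)
  if (n == 0L) return(list())
  id <- array(0L, grid$shape)
  id[idx] <- seq_len(n)
  dm <- grid$shape
  offs <- neighbour_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    src <- list(seq(max(1, 1 - d[1]), min(dm[1], dm[1] - d[1])),
                seq(max(1, 1 - d[2]), min(dm[2], dm[2] - d[2])),
                seq(max(1, 1 - d[3]), min(dm[3], dm[3] - d[3])))
    a <- id[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- id[src[[1]] + d[1], src[[2]] + d[2], src[[3]] + d[3], drop = FALSE]
    ok <- a > 0L & b > 0L
    from <- c(from, a[ok]); to <- c(to, b[ok])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  cl <- lapply(split(idx, comp), new_cluster, grid = grid)
  ext <- vapply(cl, `[[`, 0, "extent")
  first <- vapply(cl, function(x) {
    i <- x$ijk[1, ]
    (i[1] * dm[2] + i[2]) * dm[3] + i[3]  # lexicographic rank of min voxel
  }, numeric(1))
  unname(cl[order(-ext, first)])
}

#' Peak of a cluster
#'
#' The peak is the cluster voxel of maximal absolute t (signed intensity
#' is reported). When an atlas scope is given the search is restricted to
#' cluster voxels inside it, falling back to the whole cluster (label
#' `"unlabeled"`) if the intersection is empty; reporting convention is to
#' restrict to the atlas scope except for single-cluster maps. Ties are
#' broken by the lexicographically smallest voxel index.
#'
#' @param stat a `stat_map`.
#' @param cluster an `scn_cluster`.
#' @param atlas optional atlas list from [read_atlas()] for naming.
#' @param atlas_scope optional [mask_volume] restricting the peak search.
#' @return the cluster with `peak_mni`, `peak_intensity`, `peak_label`
#'   filled in.
#' @export
locate_peak <- function(stat, cluster, atlas = NULL, atlas_scope = NULL) {
  idx <- cluster$voxel_indices
  in_scope <- if (!is.null(atlas_scope)) atlas_scope$data[idx] else rep(TRUE, length(idx))
  fell_back <- FALSE
  if (!any(in_scope)) { in_scope <- rep(TRUE, length(idx)); fell_back <- TRUE }
  cand <- idx[in_scope]
  tv <- stat$t[cand]
  tv[is.na(tv)] <- 0
  best <- cand[which.max(abs(tv))]  # candidates are in lexicographic order
  ijk <- arrayInd(best, cluster$grid$shape)[1, ]
  cluster$peak_mni <- voxel_to_mni(cluster$grid, ijk)
  cluster$peak_intensity <- stat$t[best]
  cluster$peak_label <- "unlabeled"
  if (!fell_back && !is.null(atlas)) {
    lab <- atlas$labels[best]
    hit <- match(lab, atlas$lookup$label_id)
    if (lab > 0L && !is.na(hit)) cluster$peak_label <- atlas$lookup$label_name[hit]
  }
  cluster
}

#' Mean GM in a 4-mm sphere around a peak
#'
#' Convenience composition of [build_sphere_mask()] and
#' [extract_seed_values()]; used to carry peak-region volumes into the
#' cognition correlations.
#'
#' @param volumes list of [gm_volume].
#' @param peak_mni numeric(3) MNI mm.
#' @param radius_mm sphere radius, default 4.
#' @return a `seed_table`.
#' @export
extract_peak_sphere_volumes <- function(volumes, peak_mni, radius_mm = 4) {
  mask <- build_sphere_mask(peak_mni, radius_mm, volumes[[1]]$grid)
  extract_seed_values(volumes, mask,
                      seed_name = sprintf("peak(%s)", paste(peak_mni, collapse = ",")))
}

#' Cluster report table
#'
#' One row per cluster in the standard report layout: seed, contrast,
#' peak region, peak MNI x/y/z, extent (voxels) and signed peak
#' intensity, plus the corrected cluster p when available.
#'
#' @param clusters list of `scn_cluster` with peaks located.
#' @param seed,contrast labels recycled into the table.
#' @return data.frame.
#' @export
cluster_table <- function(clusters, seed = "", contrast = "") {
  if (length(clusters) == 0L)
    return(data.frame(seed = character(), contrast = character(),
                      peak_region = character(), x = numeric(), y = numeric(),
                      z = numeric(), extent = integer(),
                      peak_intensity = numeric(), corrected_p = numeric()))
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(seed = seed, contrast = contrast,
               peak_region = cl$peak_label %||% "unlabeled",
               x = cl$peak_mni[1], y = cl$peak_mni[2], z = cl$peak_mni[3],
               extent = cl$extent, peak_intensity = cl$peak_intensity,
               corrected_p = cl$corrected_p %||% NA_real_)
  }))
}
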