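test_that("separated blobs are distinct clusters and partition the mask", {
  grid <- mni_grid(c(16, 16, 16), 1.5)
  data <- array(FALSE, grid$shape)
  data[2:4, 2:4, 2:4] <- TRUE
  data[8:10, 2:4, 2:4] <- TRUE  # 3-voxel gap in x
  cl <- label_clusters(mask_volume(grid, data), 26L)
  expect_length(cl, 2)
  expect_equal(vapply(cl, `[[`, 0L, "extent"), c(27L, 27L))
  expect_equal(sum(vapply(cl, `[[`, 0L, "extent")), sum(data))
})

test_that("corner-touching voxels merge only under 26-connectivity", {
  grid <- mni_grid(c(8, 8, 8), 1.5)
  data <- array(FALSE, grid$shape)
  data[2, 2, 2] <- TRUE
  data[3, 3, 3] <- TRUE  # shares only a corner
  expect_length(label_clusters(mask_volume(grid, data), 26L), 1)
  expect_length(label_clusters(mask_volume(grid, data), 18L), 2)
  expect_length(label_clusters(mask_volume(grid, data), 6L), 2)
  # edge-touching: merges under 18 and 26, not under 6
  data2 <- array(FALSE, grid$shape)
  data2[2, 2, 2] <- TRUE
  data2[3, 3, 2] <- TRUE
  expect_length(label_clusters(mask_volume(grid, data2), 18L), 1)
  expect_length(label_clusters(mask_volume(grid, data2), 6L), 2)
})

test_that("peak location is the exhaustive argmax of |t|", {
  grid <- mni_grid(c(12, 12, 12), 1.5)
  set.seed(60)
  tarr <- array(-abs(rnorm(12^3)), grid$shape)
  mask <- array(FALSE, grid$shape); mask[3:9, 3:9, 3:9] <- TRUE
  tarr[!mask] <- NA
  tarr[5, 6, 7] <- -9.5  # unique |t| maximum
  stat <- structure(list(t = tarr, p = tarr, df = 20, tail = "negative",
                         grid = grid,
                         analysis_mask = mask_volume(grid, mask)),
                    class = "stat_map")
  cl <- label_clusters(stat$analysis_mask, 18L)[[1]]
  peaked <- locate_peak(stat, cl)
  # oracle: exhaustive scan
  best <- which.max(abs(tarr[mask]))
  expect_equal(peaked$peak_mni, voxel_to_mni(grid, c(5, 6, 7)))
  expect_equal(peaked$peak_intensity, -9.5)  # signed intensity reported
})

test_that("atlas scope restricts the peak and names it; fallback is unlabeled", {
  grid <- mni_grid(c(48, 48, 48), 1.5)
  atlas <- synthetic_atlas(grid)
  scope <- mask_volume(grid, array(atlas$labels > 0, grid$shape))
  tarr <- array(NA_real_, grid$shape)
  blob <- array(FALSE, grid$shape)
  blob[10:30, 10:24, 10:24] <- TRUE
  tarr[blob] <- 1
  inlab <- which(blob & scope$data)
  expect_gt(length(inlab), 0)
  tarr[blob] <- seq(0.1, 0.9, length.out = sum(blob))  # global max outside
  tarr[inlab[1]] <- 0.95  # scope max below a non-scope voxel elsewhere
  tarr[which(blob)[sum(blob)]] <- 5  # global max, outside scope? ensure below
  stat <- structure(list(t = tarr, p = tarr, df = 20, tail = "positive",
                         grid = grid, analysis_mask = mask_volume(grid, blob)),
                    class = "stat_map")
  cl <- label_clusters(stat$analysis_mask, 18L)[[1]]
  with_scope <- locate_peak(stat, cl, atlas = atlas, atlas_scope = scope)
  expect_true(with_scope$peak_label %in% atlas$lookup$label_name)
  expect_true(scope$data[mni_to_voxel(grid, with_scope$peak_mni)[1],
                         mni_to_voxel(grid, with_scope$peak_mni)[2],
                         mni_to_voxel(grid, with_scope$peak_mni)[3]])

  # cluster entirely outside the atlas: fallback, label "unlabeled"
  far <- array(FALSE, grid$shape); far[40:44, 40:44, 40:44] <- TRUE
  tarr2 <- array(NA_real_, grid$shape); tarr2[far] <- 2
  stat2 <- structure(list(t = tarr2, p = tarr2, df = 20, tail = "positive",
                          grid = grid, analysis_mask = mask_volume(grid, far)),
                     class = "stat_map")
  cl2 <- label_clusters(stat2$analysis_mask, 18L)[[1]]
  no_scope <- locate_peak(stat2, cl2, atlas = atlas, atlas_scope = scope)
  expect_identical(no_scope$peak_label, "unlabeled")
  expect_false(is.null(no_scope$peak_mni))
})

test_that("ties at the peak break to the lexicographically smallest voxel", {
  grid <- mni_grid(c(10, 10, 10), 1.5)
  blob <- array(FALSE, grid$shape); blob[4:6, 4:6, 4] <- TRUE
  tarr <- array(NA_real_, grid$shape); tarr[blob] <- 1
  tarr[5, 5, 4] <- 3; tarr[4, 6, 4] <- 3  # tie; (4,6,4) < (5,5,4) lexicographically
  stat <- structure(list(t = tarr, p = tarr, df = 20, tail = "positive",
                         grid = grid, analysis_mask = mask_volume(grid, blob)),
                    class = "stat_map")
  cl <- label_clusters(stat$analysis_mask, 18L)[[1]]
  expect_equal(mni_to_voxel(grid, locate_peak(stat, cl)$peak_mni),
               c(4L, 6L, 4L))
})

test_that("peak-sphere extraction equals the mask-mean composition", {
  grid <- mni_grid(c(16, 16, 16), 1.5)
  vols <- lapply(1:4, function(i) random_gm(grid, paste0("s", i), seed = i))
  peak <- c(3, -1.5, 0)
  got <- extract_peak_sphere_volumes(vols, peak)
  mask <- build_sphere_mask(peak, 4, grid)
  expect_equal(got$values, extract_seed_values(vols, mask)$values)
  const <- gm_volume("c", grid, array(0.33, grid$shape))
  expect_equal(unname(extract_peak_sphere_volumes(list(const), peak)$values),
               0.33)
})

test_that("cluster report rows are deterministic across reruns", {
  grid <- mni_grid(c(16, 16, 16), 1.5)
  set.seed(70)
  data <- array(runif(16^3) > 0.7, grid$shape)
  tarr <- array(NA_real_, grid$shape); tarr[data] <- rnorm(sum(data))
  stat <- structure(list(t = tarr, p = tarr, df = 15, tail = "positive",
                         grid = grid, analysis_mask = mask_volume(grid, data)),
                    class = "stat_map")
  run <- function() {
    cl <- label_clusters(stat$analysis_mask, 18L)
    cl <- lapply(cl, function(x) locate_peak(stat, x))
    cluster_table(cl, seed = "toy", contrast = "demo")
  }
  expect_identical(run(), run())
})
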