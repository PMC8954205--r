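trained_stub <- function(seed = 1L) {
  cfg <- tiny_model_config(seed = seed)
  structure(list(model = build_model(cfg), config = cfg),
            class = "limbicnet_trained")
}

test_that("a zero fully connected head yields an identically zero map", {
  tr <- trained_stub(seed = 2)
  tr$model$params$fc2_W[] <- 0
  v <- random_volume(tr$config$input_shape, seed = 1)
  mp <- cam(tr, v)
  expect_equal(dim(mp$weights), tr$config$input_shape)
  expect_true(all(mp$weights == 0))
})

test_that("maps scale linearly with the head weights and methods agree up to GAP", {
  tr <- trained_stub(seed = 3)
  v <- random_volume(tr$config$input_shape, seed = 2)
  m1 <- cam(tr, v)
  tr2 <- tr
  tr2$model$params$fc2_W <- 2 * tr$model$params$fc2_W
  m2 <- cam(tr2, v)
  expect_equal(m2$weights, 2 * m1$weights, tolerance = 1e-12)

  # the post-GAP head is linear, so gradient weighting differs only by the
  # constant pooling factor
  g1 <- cam(tr, v, method = "gradcam")
  fw <- limbicnet:::nn_forward(tr$model, list(v))
  expect_equal(g1$weights * prod(fw$feature_dims), m1$weights, tolerance = 1e-12)

  expect_error(cam(tr, array(0, c(2, 2, 2))), "input shape")
})

test_that("average_maps is the voxel-wise mean and rejects mixed inputs", {
  tr <- trained_stub(seed = 4)
  vs <- lapply(1:3, function(i) random_volume(tr$config$input_shape, seed = i))
  maps <- lapply(vs, function(v) cam(tr, v))
  avg <- average_maps(maps)
  expect_equal(avg$weights,
               (maps[[1]]$weights + maps[[2]]$weights + maps[[3]]$weights) / 3)
  expect_equal(average_maps(maps[1])$weights, maps[[1]]$weights)

  bad <- maps
  bad[[2]]$weights <- array(0, c(2, 2, 2))
  expect_error(average_maps(bad), "mixed dims")
  bad2 <- maps
  bad2[[2]]$crop_box <- crop_box(c(0, 0, 0), c(2, 2, 2))
  expect_error(average_maps(bad2), "mixed crop boxes")
})

test_that("region importance ranks hand-placed weight and measures leakage", {
  atl <- build_atlas(c(32, 32, 20))
  labs <- array(atl$labels, atl$dims)
  mask <- brain_mask(atl)
  hip <- match_regions(atl, "hippocampus")
  w <- array(0, atl$dims)
  hip_vox <- which(labs %in% hip)
  out_vox <- which(!mask)
  w[hip_vox[1]] <- 2
  w[out_vox[1]] <- 1
  w[hip_vox[2]] <- -5  # negative evidence must be ignored
  mp <- structure(list(weights = w, class_index = 2L, crop_box = NULL),
                  class = "activation_map")
  imp <- region_importance(mp, atl)
  expect_equal(imp$non_brain_fraction, 1 / 3)
  expect_equal(imp$ranking[1], atl$region_names[[as.character(labs[hip_vox[1]])]])
  top <- imp$table[1, ]
  expect_equal(top$mean_weight, 2 / top$n_voxels)
  # every other region carries zero positive weight
  expect_true(all(imp$table$mean_weight[-1] == 0))
})

test_that("an all-zero map gives an empty ranking and zero leakage", {
  atl <- build_atlas(c(32, 32, 20))
  mp <- structure(list(weights = array(0, atl$dims), class_index = 2L,
                       crop_box = NULL),
                  class = "activation_map")
  imp <- region_importance(mp, atl)
  expect_equal(imp$non_brain_fraction, 0)
  expect_equal(nrow(imp$table), 0)
  expect_length(imp$ranking, 0)
})

test_that("cropped maps embed at the recorded offset on the whole grid", {
  atl <- build_atlas(c(32, 32, 20))
  box <- limbic_crop_box(atl, "hippocampus", margin = 1)
  span <- box$stop - box$start
  w <- array(0, span)
  w[5, 7, 2] <- 4
  mp <- structure(list(weights = w, class_index = 2L, crop_box = box),
                  class = "activation_map")
  g <- limbicnet:::map_to_grid(mp, atl$dims)
  expect_equal(dim(g), atl$dims)
  expect_equal(g[box$start[1] + 5, box$start[2] + 7, box$start[3] + 2], 4)
  expect_equal(sum(g != 0), 1)

  # a map on a different grid than the box span is resampled into the slab
  w2 <- array(1, c(8, 8, span[3]))
  mp2 <- structure(list(weights = w2, class_index = 2L, crop_box = box),
                   class = "activation_map")
  g2 <- limbicnet:::map_to_grid(mp2, atl$dims)
  inside <- g2[(box$start[1] + 1):box$stop[1], (box$start[2] + 1):box$stop[2],
               (box$start[3] + 1):box$stop[3]]
  expect_equal(as.numeric(inside), rep(1, prod(span)))
  expect_equal(sum(g2), prod(span))

  # all positive weight inside the slab stays attributable to regions there
  imp <- region_importance(mp2, atl)
  slab_regions <- unique(array(atl$labels, atl$dims)[
    , , (box$start[3] + 1):box$stop[3]])
  hit <- imp$table$region[imp$table$mean_weight > 0]
  expect_true(all(hit %in% unlist(atl$region_names[as.character(slab_regions)])))
})

test_that("activation maps round trip through NIfTI on the whole grid", {
  atl <- build_atlas(c(32, 32, 20))
  w <- random_volume(atl$dims, seed = 9)
  mp <- structure(list(weights = w, class_index = 2L, crop_box = NULL),
                  class = "activation_map")
  path <- tempfile(fileext = ".nii.gz")
  write_activation_map(mp, atl, path)
  back <- read_volume(path)
  expect_equal(back[, , ], w[, , ], tolerance = 1e-6)
  unlink(path)
})
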