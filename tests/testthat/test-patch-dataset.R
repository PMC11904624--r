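make_dataset <- function(n = 10, seed = 1, shape = c(40, 40, 40),
                         patch = 16, ...) {
  v <- small_phantom(seed = seed, shape = shape)
  sample_patches(double_distance_map(v), n, patch_shape = patch,
                 seed = seed, ...)
}

test_that("dataset holds exactly 7N patches with seeded reproducible corners", {
  ds <- make_dataset(n = 10, seed = 4)
  expect_identical(dim(ds$patches)[4], 70L)
  expect_identical(nrow(ds$info), 70L)
  ds2 <- make_dataset(n = 10, seed = 4)
  expect_identical(ds$info[c("corner_x", "corner_y", "corner_z")],
                   ds2$info[c("corner_x", "corner_y", "corner_z")])
  expect_identical(ds$patches, ds2$patches)
})

test_that("a full-volume patch from transform 1 reproduces the exemplar map", {
  v <- random_volume(c(24, 24, 24), seed = 8)
  m <- double_distance_map(v)
  ds <- sample_patches(m, 1, patch_shape = dim(m$grid), seed = 1,
                       shift_range = 0, scale_range = 0, transforms = 1)
  expect_equal(ds$patches[, , , 1], m$grid)
  # corner bounds leave a single legal position for transform 1
  expect_identical(unlist(ds$info[1, c("corner_x", "corner_y", "corner_z")],
                          use.names = FALSE), rep(1L, 3))
})

test_that("patches larger than a transformed volume raise a named error", {
  v <- random_volume(c(24, 24, 24), seed = 8)
  m <- double_distance_map(v)
  # rotations crop, so the full input size cannot be extracted there
  expect_error(sample_patches(m, 2, patch_shape = c(24, 24, 24), seed = 1),
               "transform")
})

test_that("patch features match direct counts on constructed blocks", {
  # all-solid block
  f <- compute_patch_features(array(1.5, dim = c(4, 4, 4)), voxel_size = 6.25)
  expect_equal(unlist(f), c(porosity = 0, specific_surface_mm = 0,
                            max_pore_diameter_um = 0))
  # 4^3 block with a central 2^3 pore: porosity 8/64, 24 interface faces
  blk <- array(1.5, dim = c(4, 4, 4))
  blk[2:3, 2:3, 2:3] <- 0.5
  f <- compute_patch_features(blk, voxel_size = 6.25)
  a_mm <- 6.25 / 1000
  expect_equal(f$porosity, 8 / 64)
  expect_equal(f$specific_surface_mm, 24 / (64 * a_mm))
  # 1-voxel-wide pore slab: largest inscribed sphere spans 2 voxels
  slab <- array(1.5, dim = c(6, 6, 6))
  slab[, 3, ] <- 0.5
  f <- compute_patch_features(slab, voxel_size = 6.25)
  expect_equal(f$max_pore_diameter_um, 2 * 6.25)
  # all-pore block: inscribed diameter of the block itself
  f <- compute_patch_features(array(0.2, dim = c(4, 6, 8)), voxel_size = 2)
  expect_equal(unlist(f), c(porosity = 1, specific_surface_mm = 0,
                            max_pore_diameter_um = 4 * 2))
})

test_that("feature normalization spans [0, 1] and the filter keeps 1/8", {
  ds <- make_dataset(n = 20, seed = 5)
  for (col in c("alpha", "beta", "gamma")) {
    expect_equal(min(ds$info[[col]]), 0)
    expect_equal(max(ds$info[[col]]), 1)
  }
  fl <- filter_by_feature_target(ds, c(0.5, 0.5, 0.5))
  expect_identical(nrow(fl$info), as.integer(ceiling(140 / 8)))
  expect_identical(dim(fl$patches)[4], as.integer(ceiling(140 / 8)))
  # count conservation across sizes, including the printed 800 -> 100 case
  for (n in c(1, 7, 8, 9, 100, 800)) {
    fake <- structure(list(
      patches = array(0, dim = c(2, 2, 2, n)),
      info = tibble::tibble(patch_id = seq_len(n),
                            alpha = runif(n), beta = runif(n), gamma = runif(n)),
      patch_shape = c(2L, 2L, 2L), voxel_size = 6.25), class = "patch_dataset")
    expect_identical(nrow(filter_by_feature_target(fake, c(0.2, 0.8, 0.5))$info),
                     as.integer(ceiling(n / 8)))
  }
})

test_that("filter targets bias retained features in the requested direction", {
  ds <- make_dataset(n = 20, seed = 7)
  lo_por <- filter_by_feature_target(ds, c(0, 0.5, 0.5))
  expect_lte(mean(lo_por$info$porosity), mean(ds$info$porosity))
  big_pore <- filter_by_feature_target(ds, c(0.5, 0.5, 1))
  expect_gte(mean(big_pore$info$max_pore_diameter_um),
             mean(ds$info$max_pore_diameter_um))
  # order-statistics oracle on a synthetic feature table: target alpha = 0
  # must retain the patches with the smallest alpha when beta/gamma are tied
  n <- 64
  fake <- structure(list(
    patches = array(0, dim = c(2, 2, 2, n)),
    info = tibble::tibble(patch_id = seq_len(n),
                          porosity = seq(0, 1, length.out = n),
                          alpha = seq(0, 1, length.out = n),
                          beta = 0.5, gamma = 0.5),
    patch_shape = c(2L, 2L, 2L), voxel_size = 6.25), class = "patch_dataset")
  kept <- filter_by_feature_target(fake, c(0, 0.5, 0.5))$info$patch_id
  expect_identical(kept, 1:8)
})

test_that("a symmetric dataset filtered at the centre stays symmetric", {
  n <- 16
  alpha <- c(seq(0.1, 0.45, length.out = 8), 1 - seq(0.1, 0.45, length.out = 8))
  fake <- structure(list(
    patches = array(0, dim = c(2, 2, 2, n)),
    info = tibble::tibble(patch_id = seq_len(n), alpha = alpha,
                          beta = 0.5, gamma = 0.5),
    patch_shape = c(2L, 2L, 2L), voxel_size = 6.25), class = "patch_dataset")
  kept <- filter_by_feature_target(fake, c(0.5, 0.5, 0.5))$info
  expect_equal(mean(kept$alpha), 0.5)
})
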