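test_that("placement grid follows corner arithmetic with a clamped last corner", {
  cfg <- reconstruction_config(c(100, 100, 100), patch_shape = 20, margin = 6)
  expect_identical(cfg$delta, rep(8L, 3))
  g <- placement_grid(cfg, randomize = FALSE)
  expect_setequal(unique(g$x), 6 + 8 * (0:10))
  # windows cover the full output: last window ends at S
  expect_equal(max(g$x) - 6 + 20, 100)
  # degenerate single placement
  cfg1 <- reconstruction_config(c(20, 20, 20), patch_shape = 20, margin = 0)
  g1 <- placement_grid(cfg1)
  expect_identical(nrow(g1), 1L)
  expect_identical(unlist(g1[1, c("x", "y", "z")], use.names = FALSE),
                   rep(0L, 3))
  # seeded permutation is reproducible
  cfg2 <- reconstruction_config(c(64, 64, 64), patch_shape = 16, margin = 4,
                                seed = 42)
  expect_identical(placement_grid(cfg2), placement_grid(cfg2))
  expect_error(reconstruction_config(c(64, 64, 64), patch_shape = 12, margin = 6),
               "positive")
})

test_that("matching error is a masked mean absolute difference", {
  a <- array(c(1, 2), dim = c(2, 1, 1))
  b <- array(c(1.5, 2.5), dim = c(2, 1, 1))
  m_all <- array(TRUE, dim = c(2, 1, 1))
  expect_equal(matching_error(a, b, m_all), 0.5)
  expect_equal(matching_error(a, a, m_all), 0)
  expect_identical(matching_error(a, b, array(FALSE, dim = c(2, 1, 1))),
                   NA_real_)
  expect_error(matching_error(a, array(1, dim = c(3, 1, 1)), m_all), "shape")
})

test_that("best-patch selection agrees with independent exhaustive recomputation", {
  set.seed(31)
  cfg <- reconstruction_config(c(16, 16, 16), patch_shape = 8, margin = 2,
                               seed = 5)
  canvas <- new_canvas(cfg)
  corner <- c(2L, 2L, 2L)
  idx <- fibrosynth:::window_index(cfg, corner)
  win_vals <- array(runif(8^3, 0, 2), dim = c(8, 8, 8))
  occ <- array(runif(8^3) < 0.4, dim = c(8, 8, 8))
  canvas$values[idx$x, idx$y, idx$z] <- win_vals
  canvas$occupancy[idx$x, idx$y, idx$z] <- occ
  patches <- array(runif(8^3 * 5, 0, 2), dim = c(8, 8, 8, 5))
  ds <- structure(list(patches = patches,
                       info = tibble::tibble(patch_id = 1:5),
                       patch_shape = c(8L, 8L, 8L), voxel_size = 6.25),
                  class = "patch_dataset")
  sel <- select_best_patch(canvas, corner, ds, cfg)
  # brute-force oracle
  errs <- vapply(1:5, function(p)
    matching_error(win_vals, patches[, , , p], occ), numeric(1))
  expect_identical(sel$index, which.min(errs))
  expect_equal(sel$error, min(errs))
  # an exact copy of the window wins with zero error
  patches[, , , 3] <- win_vals
  ds$patches <- patches
  sel <- select_best_patch(canvas, corner, ds, cfg)
  expect_identical(sel$index, 3L)
  expect_equal(sel$error, 0)
  # empty canvas: uniform random index, reproducible under seed
  empty <- new_canvas(cfg)
  i1 <- withr::with_seed(7, select_best_patch(empty, corner, ds, cfg))
  i2 <- withr::with_seed(7, select_best_patch(empty, corner, ds, cfg))
  expect_identical(i1, i2)
  expect_true(is.na(i1$error))
})

test_that("blending writes patches verbatim on empty ground and preserves interiors", {
  cfg <- reconstruction_config(c(32, 32, 32), patch_shape = 12, margin = 3,
                               seed = 1)
  canvas <- new_canvas(cfg)
  patch <- array(runif(12^3, 0, 2), dim = c(12, 12, 12))
  corner <- c(3L, 3L, 3L)
  canvas2 <- blend_patch(canvas, corner, patch, cfg)
  idx <- fibrosynth:::window_index(cfg, corner)
  expect_equal(canvas2$values[idx$x, idx$y, idx$z], patch)
  expect_true(all(canvas2$occupancy[idx$x, idx$y, idx$z]))
  # fully occupied canvas: voxels deeper than one margin keep prior values
  full <- new_canvas(cfg)
  full$values[] <- 1.25
  full$occupancy[] <- TRUE
  out <- blend_patch(full, corner, patch, cfg)
  win <- out$values[idx$x, idx$y, idx$z]
  interior <- array(FALSE, dim = c(12, 12, 12))
  interior[4:9, 4:9, 4:9] <- TRUE # deeper than margin 3 from every side
  expect_true(all(win[interior] == 1.25))
  expect_false(all(win == 1.25)) # borders took patch influence
})

test_that("half-occupied windows blend monotonically from prior to patch", {
  cfg <- reconstruction_config(c(32, 32, 32), patch_shape = 12, margin = 3,
                               seed = 1)
  canvas <- new_canvas(cfg)
  corner <- c(3L, 3L, 3L)
  idx <- fibrosynth:::window_index(cfg, corner)
  canvas$values[1:9, , ] <- 2 # occupied half (6 content voxels + offset 3)
  canvas$occupancy[1:9, , ] <- TRUE
  patch <- array(0, dim = c(12, 12, 12))
  out <- blend_patch(canvas, corner, patch, cfg)
  profile <- out$values[idx$x, 6, 6]
  expect_equal(max(profile), 2)            # deep occupied voxels keep prior
  expect_equal(profile[12], 0)             # unoccupied side is pure patch
  # monotone ramp from the deepest occupied voxel down to the patch side
  tail_ramp <- profile[which.max(profile):12]
  expect_true(all(diff(tail_ramp) <= 1e-12))
})

test_that("reconstruction reproduces a striped exemplar's porosity", {
  v <- striped_volume(c(32, 32, 32), w = 4)
  ds <- sample_patches(double_distance_map(v), 15, patch_shape = 12, seed = 2)
  por <- vapply(1:10, function(k) {
    cfg <- reconstruction_config(c(32, 32, 32), patch_shape = 12, margin = 3,
                                 sigma = 0.5, seed = 200 + k)
    porosity(reconstruct_volume(ds, cfg)$volume)
  }, numeric(1))
  expect_lt(abs(mean(por) - porosity(v)), 0.05)
})

test_that("reconstruction is deterministic and visits every grid cell once", {
  v <- small_phantom(seed = 4, shape = c(40, 40, 40))
  ds <- sample_patches(double_distance_map(v), 10, patch_shape = 16, seed = 1)
  cfg <- reconstruction_config(c(40, 40, 40), patch_shape = 16, margin = 4,
                               seed = 9, feature_target = c(0.5, 0.5, 0.5))
  r1 <- reconstruct_volume(ds, cfg)
  r2 <- reconstruct_volume(ds, cfg)
  expect_identical(r1$volume$grid, r2$volume$grid)
  expect_identical(r1$matching, r2$matching)
  # termination: one visit per grid cell, full coverage after crop
  expect_identical(nrow(r1$matching), nrow(placement_grid(cfg)))
  expect_identical(dim(r1$volume$grid), cfg$output_shape)
  expect_false(anyDuplicated(r1$matching[c("x", "y", "z")]) > 0)
  # overlap-quality diagnostic is a valid fraction
  expect_gte(r1$fraction_matched, 0)
  expect_lte(r1$fraction_matched, 1)
  # a few early placements land on empty ground; most are constrained
  n_free <- sum(is.na(r1$matching$error))
  expect_gte(n_free, 1L)
  expect_lt(n_free / nrow(r1$matching), 0.25)
})

test_that("feature targets steer reconstruction porosity in the right direction", {
  v <- small_phantom(seed = 8, shape = c(48, 48, 48))
  ds <- sample_patches(double_distance_map(v), 40, patch_shape = 16, seed = 3)
  por <- function(target, seed) {
    cfg <- reconstruction_config(c(48, 48, 48), patch_shape = 16, margin = 4,
                                 seed = seed, feature_target = target)
    porosity(reconstruct_volume(ds, cfg)$volume)
  }
  lo <- mean(vapply(1:2, function(k) por(c(0, 0.5, 0.5), 300 + k), numeric(1)))
  hi <- mean(vapply(1:2, function(k) por(c(1, 0.5, 0.5), 300 + k), numeric(1)))
  expect_lt(lo, hi)
})
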