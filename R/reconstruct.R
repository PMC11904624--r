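#' Reconstruction configuration
#'
#' Collects the geometry and randomness parameters for patch-quilting
#' reconstruction. Patches of size `patch_shape` are placed on a regular grid
#' with spacing `delta = patch_shape - 2 * margin` per axis, so neighbouring
#' patches overlap by `2 * margin` voxels; `margin` (typically 6) controls
#' how much context each placement must match and blend against.
#'
#' @param output_shape Desired output volume size `(S1, S2, S3)` in voxels.
#' @param patch_shape Patch size in voxels (length 1 or 3); must exceed
#'   `2 * margin`.
#' @param margin Overlap margin `m` in voxels (default 6).
#' @param sigma Gaussian smoothing (voxels) applied before the final
#'   threshold (default 0.5, just enough to heal seams between patches).
#' @param seed Integer seed; drives placement order and first-patch choice.
#' @param feature_target Optional `(alpha, beta, gamma)` target passed to
#'   [filter_by_feature_target()] before reconstruction; `NULL` uses the
#'   dataset as given.
#' @return A `reconstruction_config` object.
#' @export
reconstruction_config <- function(output_shape, patch_shape = c(24, 24, 24),
                                  margin = 6, sigma = 0.5, seed = 1,
                                  feature_target = NULL) {
  if (length(output_shape) == 1L) output_shape <- rep(output_shape, 3)
  if (length(patch_shape) == 1L) patch_shape <- rep(patch_shape, 3)
  output_shape <- as.integer(output_shape)
  patch_shape <- as.integer(patch_shape)
  margin <- as.integer(margin)
  stopifnot(length(output_shape) == 3L, length(patch_shape) == 3L,
            all(output_shape > 0L), margin >= 0L, sigma >= 0)
  delta <- patch_shape - 2L * margin
  if (any(delta <= 0L))
    stop("grid spacing patch_shape - 2 * margin must be positive", call. = FALSE)
  if (any(output_shape < patch_shape))
    stop("`output_shape` must be at least `patch_shape` on every axis", call. = FALSE)
  if (!is.null(feature_target)) stopifnot(length(feature_target) == 3L)
  structure(list(output_shape = output_shape, patch_shape = patch_shape,
                 margin = margin, delta = delta, sigma = sigma,
                 seed = as.integer(seed), feature_target = feature_target),
            class = "reconstruction_config")
}

axis_starts <- function(S, s, delta) {
  st <- seq.int(0L, max(S - s, 0L), by = delta)
  if (st[length(st)] != S - s) st <- c(st, S - s)
  st
}

#' Placement grid for patch quilting
#'
#' Computes the patch placement corners `m + n * delta` on each axis (with a
#' final corner clamped so patch windows reach the far face) and returns them
#' in a seeded uniformly random order.
#'
#' @param config A [reconstruction_config()].
#' @param randomize Return the corners in seeded random order (default) or in
#'   raster order.
#' @return A tibble with 0-based corner offsets `x`, `y`, `z` (the patch
#'   window spans `corner - margin` to `corner - margin + patch_shape` on
#'   each axis) and the placement `order`.
#' @export
placement_grid <- function(config, randomize = TRUE) {
  stopifnot(inherits(config, "reconstruction_config"))
  g <- expand.grid(
    x = axis_starts(config$output_shape[1], config$patch_shape[1], config$delta[1]) + config$margin,
    y = axis_starts(config$output_shape[2], config$patch_shape[2], config$delta[2]) + config$margin,
    z = axis_starts(config$output_shape[3], config$patch_shape[3], config$delta[3]) + config$margin)
  g <- tibble::as_tibble(g)
  if (randomize) {
    perm <- withr::with_seed(config$seed, sample.int(nrow(g)))
    g <- g[perm, ]
  }
  g$order <- seq_len(nrow(g))
  g
}

#' Create an empty reconstruction canvas
#'
#' The working volume extends the requested output shape by one patch length
#' plus two margins per axis so that clamped final placements and
#' margin-extended matching windows never run out of room; it is cropped back
#' to `output_shape` at the end. Occupancy is tracked with an explicit
#' boolean mask rather than a zero-value test, since a legitimate
#' double-distance value can be exactly 0.
#'
#' @param config A [reconstruction_config()].
#' @return A `recon_canvas` with `values` and `occupancy` arrays; the content
#'   region starts `margin` voxels into each axis.
#' @export
new_canvas <- function(config) {
  ext <- config$output_shape + config$patch_shape + 2L * config$margin
  structure(list(values = array(0, dim = ext),
                 occupancy = array(FALSE, dim = ext),
                 offset = config$margin),
            class = "recon_canvas")
}

# patch footprint of a placement corner, in canvas array indices
# (content voxel c, 0-based, lives at array index c + margin + 1)
window_index <- function(config, corner) {
  lo <- corner + 1L # = (corner - margin) + margin + 1
  list(x = lo[1]:(lo[1] + config$patch_shape[1] - 1L),
       y = lo[2]:(lo[2] + config$patch_shape[2] - 1L),
       z = lo[3]:(lo[3] + config$patch_shape[3] - 1L))
}


#' Masked matching error between a canvas subsample and a candidate patch
#'
#' Mean absolute difference over the voxels where `mask` is `TRUE` (the
#' already-occupied overlap region). An all-`FALSE` mask carries no
#' constraint and yields `NA` rather than a number; callers resolve it by
#' choosing a patch at random.
#'
#' @param subsample,candidate Numeric arrays of identical shape.
#' @param mask Logical array of the same shape.
#' @return A scalar error, or `NA_real_` when the mask is empty.
#' @export
matching_error <- function(subsample, candidate, mask) {
  if (!identical(dim(subsample), dim(candidate)) ||
      !identical(dim(subsample), dim(mask)))
    stop("subsample, candidate and mask must share the same shape", call. = FALSE)
  if (!any(mask)) return(NA_real_)
  mean(abs(subsample[mask] - candidate[mask]))
}

#' Select the best-matching patch for a placement
#'
#' Exhaustively scans the dataset for the patch minimizing the masked mean
#' absolute difference against the canvas window at `corner` (the patch
#' footprint; previously placed neighbours overlap it by twice the margin, so
#' that band is where the error is measured); ties go to the lowest index.
#' When the window has no occupied voxel (the first placement), a uniformly
#' random index is drawn from the current RNG stream.
#'
#' @param canvas A `recon_canvas`.
#' @param corner 0-based corner offsets (a row of [placement_grid()]).
#' @param dataset A `patch_dataset`.
#' @param config A [reconstruction_config()].
#' @return A list with `index` (1-based patch index) and `error` (the
#'   winning matching error, `NA` for an unconstrained placement).
#' @export
select_best_patch <- function(canvas, corner, dataset, config) {
  np <- dim(dataset$patches)[4]
  idx <- window_index(config, as.integer(corner))
  win <- canvas$values[idx$x, idx$y, idx$z]
  occ <- canvas$occupancy[idx$x, idx$y, idx$z]
  if (!any(occ))
    return(list(index = sample.int(np, 1L), error = NA_real_))
  res <- cpp_match_scan(as.numeric(dataset$patches), as.numeric(win),
                        as.logical(occ))
  list(index = res$best, error = res$error)
}

#' Blend a patch into the canvas with distance-based weights
#'
#' Writes `window <- window * w + patch * (1 - w)` where `w` is the Euclidean
#' distance of each occupied voxel into the occupied region (distance to the
#' nearest unoccupied voxel, with the window border treated as unoccupied),
#' divided by the overlap margin and capped at 1. Unoccupied voxels have
#' `w = 0` and take the patch value verbatim; occupied voxels deeper than one
#' margin length keep their prior values exactly (`w = 1`), so the
#' patch-vs-prior interpolation is confined to the designed overlap band near
#' the block borders and previously settled material is never degraded by
#' later placements.
#'
#' @param canvas A `recon_canvas`.
#' @param corner 0-based corner offsets.
#' @param patch A numeric array of shape `config$patch_shape`.
#' @param config A [reconstruction_config()].
#' @return The updated canvas (occupancy of the window becomes `TRUE`).
#' @export
blend_patch <- function(canvas, corner, patch, config) {
  idx <- window_index(config, as.integer(corner))
  win <- canvas$values[idx$x, idx$y, idx$z]
  occ <- canvas$occupancy[idx$x, idx$y, idx$z]
  s <- dim(patch)
  stopifnot(identical(as.integer(s), as.integer(dim(win))))
  if (any(occ)) {
    pad <- array(FALSE, dim = s + 2L)
    pad[2:(s[1] + 1L), 2:(s[2] + 1L), 2:(s[3] + 1L)] <- occ
    d <- edt(pad)[2:(s[1] + 1L), 2:(s[2] + 1L), 2:(s[3] + 1L)]
    w <- pmin(d / max(config$margin, 1L), 1)
    new_vals <- win * w + patch * (1 - w)
  } else {
    new_vals <- patch
  }
  canvas$values[idx$x, idx$y, idx$z] <- new_vals
  canvas$occupancy[idx$x, idx$y, idx$z] <- TRUE
  canvas
}

#' Reconstruct a new volume from a patch dataset
#'
#' Runs the full quilting loop: visit every placement-grid cell in seeded
#' random order, pick the best-matching patch by exhaustive scan
#' ([select_best_patch()]), blend it in ([blend_patch()]); finally crop the
#' canvas to the requested shape, smooth with a Gaussian of `config$sigma`
#' voxels and threshold at 1 to recover a binary volume. The whole procedure
#' is deterministic for a fixed dataset, configuration and seed.
#'
#' @param dataset A `patch_dataset` whose `patch_shape` matches the config.
#' @param config A [reconstruction_config()]. If `config$feature_target` is
#'   set, the dataset is first filtered with [filter_by_feature_target()].
#' @return A `fibro_recon` object: `volume` (the binary reconstruction),
#'   `matching` (a tibble of per-placement corners, chosen patch indices and
#'   matching errors), `fraction_matched` (share of constrained placements
#'   with error below 0.2, the standard matching-quality diagnostic),
#'   `config` and `dataset_size`.
#' @examples
#' v <- generate_fibrous_volume(phantom_spec(shape = c(48, 48, 48), seed = 4))
#' ds <- sample_patches(double_distance_map(v), 20, patch_shape = 16, seed = 1)
#' rec <- reconstruct_volume(ds, reconstruction_config(c(48, 48, 48),
#'                           patch_shape = 16, margin = 4, seed = 7))
#' porosity(rec$volume)
#' @export
reconstruct_volume <- function(dataset, config) {
  stopifnot(inherits(dataset, "patch_dataset"),
            inherits(config, "reconstruction_config"))
  if (!identical(as.integer(dataset$patch_shape), config$patch_shape))
    stop("dataset patch_shape does not match config patch_shape", call. = FALSE)
  if (!is.null(config$feature_target))
    dataset <- filter_by_feature_target(dataset, config$feature_target)
  S <- config$output_shape
  res <- withr::with_seed(config$seed, {
    grid <- placement_grid_current_rng(config)
    canvas <- new_canvas(config)
    errors <- numeric(nrow(grid))
    chosen <- integer(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      corner <- c(grid$x[r], grid$y[r], grid$z[r])
      sel <- select_best_patch(canvas, corner, dataset, config)
      chosen[r] <- sel$index
      errors[r] <- sel$error
      canvas <- blend_patch(canvas, corner,
                            dataset$patches[, , , sel$index, drop = TRUE], config)
    }
    list(canvas = canvas, grid = grid, errors = errors, chosen = chosen)
  })
  m <- config$margin
  cx <- m + seq_len(S[1]); cy <- m + seq_len(S[2]); cz <- m + seq_len(S[3])
  cropped <- res$canvas$values[cx, cy, cz]
  stopifnot(all(res$canvas$occupancy[cx, cy, cz]))
  vol <- threshold_to_binary(array(cropped, dim = S), sigma = config$sigma,
                             voxel_size = dataset$voxel_size)
  matching <- res$grid
  matching$patch <- res$chosen
  matching$error <- res$errors
  constrained <- matching$error[!is.na(matching$error)]
  structure(list(volume = vol,
                 matching = matching,
                 fraction_matched = if (length(constrained)) mean(constrained < 0.2) else NA_real_,
                 config = config,
                 dataset_size = dim(dataset$patches)[4]),
            class = "fibro_recon")
}

# placement grid drawing its permutation from the current RNG stream, so the
# whole reconstruction consumes one seeded stream.
placement_grid_current_rng <- function(config) {
  g <- placement_grid(config, randomize = FALSE)
  g <- g[sample.int(nrow(g)), ]
  g$order <- seq_len(nrow(g))
  g
}

#' @export
#' @method print fibro_recon
print.fibro_recon <- function(x, ...) {
  d <- dim(x$volume$grid)
  cat(sprintf(paste0("<fibro_recon> %d x %d x %d voxels, porosity %.3f, ",
                     "%d placements, %.0f%% matched below 0.2\n"),
              d[1], d[2], d[3], porosity(x$volume), nrow(x$matching),
              100 * x$fraction_matched))
  invisible(x)
}
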