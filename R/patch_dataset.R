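#' Per-patch morphological features
#'
#' Thresholds a grayscale patch at 1 (no smoothing) and measures three
#' features of the resulting binary block: porosity (pore voxel fraction),
#' specific surface area (solid-pore face count per unit volume, 1/mm) and
#' maximum pore diameter (twice the largest pore-phase Euclidean distance to
#' solid, micrometres). Single-phase patches are legal: an all-solid patch
#' yields `(0, 0, 0)`; an all-pore patch yields porosity 1, specific surface
#' 0 and the inscribed diameter of the whole patch.
#'
#' @param patch A 3D numeric array (grayscale, double-distance scale).
#' @param voxel_size Voxel edge length in micrometres.
#' @return A one-row [tibble::tibble()] with columns `porosity`,
#'   `specific_surface_mm` and `max_pore_diameter_um`.
#' @export
compute_patch_features <- function(patch, voxel_size = 6.25) {
  stopifnot(is.array(patch), length(dim(patch)) == 3L)
  v <- binary_volume(array(patch > 1, dim = dim(patch)), voxel_size = voxel_size)
  tibble::tibble(porosity = porosity(v),
                 specific_surface_mm = specific_surface(v),
                 max_pore_diameter_um = max_pore_diameter(v))
}

#' Build a diversified patch dataset from a double distance map
#'
#' Applies the seven transformations of [apply_transform()] (each with its
#' own random intensity shift and scale, drawn once per transformed volume),
#' extracts `n_per_transform` cubic patches at uniformly random corners from
#' each transformed map, and computes per-patch features together with their
#' min-max normalized coordinates `alpha` (porosity), `beta` (specific
#' surface) and `gamma` (maximum pore size), each scaled to `[0, 1]` over the
#' full dataset. The resulting dataset of `7 * n_per_transform` patches is the
#' raw material for [reconstruct_volume()].
#'
#' @param map A `double_distance_map` (the exemplar representation).
#' @param n_per_transform Number of patches sampled from each transformed
#'   volume.
#' @param patch_shape Patch size in voxels along each axis (length 1 or 3).
#' @param seed Integer seed controlling shift/scale draws and patch corners.
#' @param shift_range Half-width of the uniform intensity-shift draw
#'   (default 0.1 units); 0 disables shifting.
#' @param scale_range Half-width of the uniform intensity-scale draw about 1
#'   (default 0.1, i.e. plus or minus 10 percent); 0 disables scaling.
#' @param transforms Which of the seven transforms to draw from (default all;
#'   the dataset then has `7 * n_per_transform` patches).
#' @return A `patch_dataset`: a list with `patches` (a 4D array
#'   `s1 x s2 x s3 x n`), `info` (a tibble with provenance, features and
#'   normalized features per patch), `patch_shape`, `voxel_size` and the
#'   frozen `norm_ranges` used for feature normalization.
#' @examples
#' v <- generate_fibrous_volume(phantom_spec(shape = c(48, 48, 48), seed = 3))
#' d <- sample_patches(double_distance_map(v), n_per_transform = 5,
#'                     patch_shape = 16, seed = 1)
#' dim(d$patches)
#' @export
sample_patches <- function(map, n_per_transform, patch_shape = c(24, 24, 24),
                           seed = 1, shift_range = 0.1, scale_range = 0.1,
                           transforms = 1:7) {
  stopifnot(inherits(map, "double_distance_map"),
            shift_range >= 0, scale_range >= 0,
            all(transforms %in% 1:7), !anyDuplicated(transforms))
  transforms <- as.integer(transforms)
  if (length(patch_shape) == 1L) patch_shape <- rep(patch_shape, 3)
  patch_shape <- as.integer(patch_shape)
  n_per_transform <- as.integer(n_per_transform)
  stopifnot(n_per_transform >= 1L, all(patch_shape >= 2L))
  s <- patch_shape
  ntot <- length(transforms) * n_per_transform
  patches <- array(0, dim = c(s, ntot))
  info <- vector("list", length(transforms))
  withr::with_seed(seed, {
    for (t_idx in seq_along(transforms)) {
      i <- transforms[t_idx]
      shift <- runif(1, -shift_range, shift_range)
      scale <- runif(1, 1 - scale_range, 1 + scale_range)
      tm <- apply_transform(map, i, shift = shift, scale = scale)
      dt <- dim(tm$grid)
      if (any(dt < s))
        stop(sprintf("patch %s too large for transform %d volume %s",
                     paste(s, collapse = "x"), i, paste(dt, collapse = "x")),
             call. = FALSE)
      cx <- sample.int(dt[1] - s[1] + 1L, n_per_transform, replace = TRUE)
      cy <- sample.int(dt[2] - s[2] + 1L, n_per_transform, replace = TRUE)
      cz <- sample.int(dt[3] - s[3] + 1L, n_per_transform, replace = TRUE)
      for (n in seq_len(n_per_transform)) {
        patches[, , , (t_idx - 1L) * n_per_transform + n] <-
          tm$grid[cx[n]:(cx[n] + s[1] - 1L),
                  cy[n]:(cy[n] + s[2] - 1L),
                  cz[n]:(cz[n] + s[3] - 1L)]
      }
      info[[t_idx]] <- tibble::tibble(transform = i, corner_x = cx, corner_y = cy,
                                  corner_z = cz, shift = shift, scale = scale)
    }
  })
  info <- dplyr::bind_rows(info)
  info$patch_id <- seq_len(ntot)
  feats <- lapply(seq_len(ntot), function(p)
    compute_patch_features(patches[, , , p, drop = TRUE], map$voxel_size))
  feats <- dplyr::bind_rows(feats)
  info <- dplyr::bind_cols(info[, c("patch_id", "transform", "corner_x",
                                    "corner_y", "corner_z", "shift", "scale")],
                           feats)
  rng <- lapply(feats, range)
  minmax <- function(x, r) if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0.5, length(x))
  info$alpha <- minmax(feats$porosity, rng$porosity)
  info$beta <- minmax(feats$specific_surface_mm, rng$specific_surface_mm)
  info$gamma <- minmax(feats$max_pore_diameter_um, rng$max_pore_diameter_um)
  structure(list(patches = patches, info = info, patch_shape = s,
                 voxel_size = map$voxel_size, norm_ranges = rng),
            class = "patch_dataset")
}

#' @export
#' @method print patch_dataset
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches of %s voxels @ %.3g um\n",
              dim(x$patches)[4], paste(x$patch_shape, collapse = "x"),
              x$voxel_size))
  invisible(x)
}

#' Feature table of a patch dataset
#'
#' @param dataset A `patch_dataset`.
#' @return The per-patch provenance/feature tibble (one row per patch).
#' @export
feature_table <- function(dataset) {
  stopifnot(inherits(dataset, "patch_dataset"))
  dataset$info
}

#' Filter a patch dataset towards a feature-space target
#'
#' Retains the eighth of the dataset (rounded up) whose normalized feature
#' coordinates `(alpha, beta, gamma)` are closest, in Euclidean distance, to
#' the target point - a sphere in the unit feature cube. The centre target
#' `c(0.5, 0.5, 0.5)` yields an unbiased dataset that statistically matches
#' the exemplar; off-centre targets bias reconstructions towards, for
#' example, lower porosity (`alpha` near 0) or larger pores (`gamma` near 1).
#' Distance ties are broken in favour of earlier patches. The normalization
#' frame of the unfiltered dataset is kept frozen, so targets are
#' reproducible.
#'
#' @param dataset A `patch_dataset`.
#' @param target Numeric length-3 vector `(alpha, beta, gamma)`, each in
#'   `[0, 1]`.
#' @return A `patch_dataset` containing `ceiling(n / 8)` patches, in their
#'   original order; the target is recorded as attribute `feature_target`.
#' @export
filter_by_feature_target <- function(dataset, target) {
  stopifnot(inherits(dataset, "patch_dataset"))
  target <- as.numeric(target)
  if (length(target) != 3L || any(target < 0) || any(target > 1))
    stop("`target` must be 3 values in [0, 1]", call. = FALSE)
  n <- nrow(dataset$info)
  stopifnot(n >= 1L)
  d2 <- (dataset$info$alpha - target[1])^2 +
        (dataset$info$beta - target[2])^2 +
        (dataset$info$gamma - target[3])^2
  k <- ceiling(n / 8)
  keep <- sort(order(d2, seq_len(n))[seq_len(k)])
  out <- dataset
  out$patches <- dataset$patches[, , , keep, drop = FALSE]
  out$info <- dataset$info[keep, ]
  attr(out, "feature_target") <- target
  out
}
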