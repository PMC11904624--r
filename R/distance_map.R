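#' Double distance map of a binary volume
#'
#' Converts a two-phase binary volume into the spatially correlated grayscale
#' field used for synthesis,
#' \deqn{I = \hat d(I_0) - \hat d(1 - I_0) + 1,}
#' where \eqn{I_0} is the binary volume (solid = 1) and \eqn{\hat d} is the
#' Euclidean distance transform to the opposite phase, normalized by its own
#' maximum over the volume (per phase). Values lie on a continuous scale from
#' 0 (deep pore) through 1 (interface) to 2 (deep solid), which makes the
#' microstructure interpolatable: rotations, blends and averages of the map
#' remain meaningful, unlike direct operations on the binary grid.
#'
#' Distances are measured from each in-phase voxel to the nearest voxel
#' *centre* of the opposite phase, so interface-adjacent voxels get distance
#' 1 (never 0). Solid voxels therefore map strictly above 1 and pore voxels
#' strictly below 1, making [threshold_to_binary()] with `sigma = 0` an exact
#' inverse.
#'
#' Two normalization conventions are offered. `"shared"` (the default)
#' divides both distance fields by their common maximum, which gives the map
#' the same gradient magnitude on both sides of the interface; this keeps
#' grayscale-averaging operations (rotation, blending, smoothing) from
#' systematically displacing the interface towards the thinner phase, at the
#' cost of the map not always attaining the end of the scale on the shallower
#' phase. `"per_phase"` divides each field by its own maximum, so the map
#' always attains both 0 and 2 on any two-phase volume.
#'
#' @param volume A [binary_volume()] containing at least one voxel of each
#'   phase.
#' @param normalization `"shared"` (symmetric gradients, default) or
#'   `"per_phase"` (full 0-2 span).
#' @return A `double_distance_map` object (fields `grid`, `voxel_size`).
#' @seealso [threshold_to_binary()]
#' @examples
#' v <- binary_volume(array(rep(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE), 1),
#'                          dim = c(6, 1, 1)))
#' double_distance_map(v)$grid[, 1, 1]
#' @export
double_distance_map <- function(volume, normalization = c("shared", "per_phase")) {
  stopifnot(inherits(volume, "binary_volume"))
  normalization <- match.arg(normalization)
  g <- volume$grid
  if (all(g) || !any(g))
    stop("degenerate phase: both solid and pore voxels are required", call. = FALSE)
  ds <- edt(g)    # distance from solid voxels to nearest pore voxel
  dp <- edt(!g)   # distance from pore voxels to nearest solid voxel
  i <- if (normalization == "per_phase") {
    ds / max(ds) - dp / max(dp) + 1
  } else {
    mx <- max(max(ds), max(dp))
    ds / mx - dp / mx + 1
  }
  new_double_distance_map(i, volume$voxel_size)
}

#' Threshold a double distance map back to a binary volume
#'
#' Optionally smooths the map with an isotropic Gaussian of standard
#' deviation `sigma` (in voxels), then classifies voxels by
#' \eqn{(G_\sigma(I) - 1) > 0}: values above 1 become solid, values at or
#' below 1 become pore. With `sigma = 0` this exactly inverts
#' [double_distance_map()]. A small `sigma` (typically 0.5) removes minor
#' discontinuities between quilted patches while preserving texture.
#'
#' @param map A `double_distance_map` (or 3D numeric array plus `voxel_size`).
#' @param sigma Gaussian smoothing standard deviation in voxels; `0` disables
#'   smoothing. Must be non-negative.
#' @param voxel_size Voxel size in micrometres, used only when `map` is a bare
#'   array.
#' @return A [binary_volume()].
#' @export
threshold_to_binary <- function(map, sigma = 0, voxel_size = NULL) {
  if (inherits(map, "double_distance_map")) {
    g <- map$grid
    vs <- map$voxel_size
  } else if (is.array(map) && length(dim(map)) == 3L) {
    g <- map
    vs <- if (is.null(voxel_size)) 6.25 else voxel_size
  } else stop("`map` must be a double_distance_map or a 3D array", call. = FALSE)
  if (!all(is.finite(g))) stop("map values must be finite", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a non-negative scalar", call. = FALSE)
  if (sigma > 0)
    g <- array(cpp_gauss3(as.numeric(g), as.integer(dim(g)), sigma), dim = dim(g))
  binary_volume(array((g - 1) > 0, dim = dim(g)), voxel_size = vs)
}

# Isotropic Gaussian smoothing of a 3D array (sigma in voxels).
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  array(cpp_gauss3(as.numeric(x), as.integer(dim(x)), sigma), dim = dim(x))
}
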