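#' Binary voxel volume
#'
#' Container for a 3D two-phase microstructure: a logical voxel grid where
#' `TRUE` marks the solid phase (fibres) and `FALSE` the pore space, plus the
#' physical voxel edge length in micrometres. This is the common currency of
#' the package: phantoms, thresholded reconstructions and micro-CT stacks all
#' arrive as binary volumes.
#'
#' @param grid A 3D `logical` (or coercible 0/1 numeric) array; `TRUE`/1 =
#'   solid, `FALSE`/0 = pore.
#' @param voxel_size Voxel edge length in micrometres. Defaults to 6.25, a
#'   typical desktop micro-CT resolution for soft-tissue scans.
#' @return An object of class `binary_volume` with fields `grid` and
#'   `voxel_size`.
#' @examples
#' v <- binary_volume(array(c(TRUE, FALSE), dim = c(4, 4, 4)))
#' porosity(v)
#' @export
binary_volume <- function(grid, voxel_size = 6.25) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (!is.logical(grid)) {
    if (!all(grid %in% c(0, 1)))
      stop("numeric `grid` must contain only 0 (pore) and 1 (solid)", call. = FALSE)
    grid <- array(as.logical(grid), dim = dim(grid))
  }
  if (anyNA(grid)) stop("`grid` must not contain NA", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (micrometres)", call. = FALSE)
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "binary_volume")
}

new_double_distance_map <- function(grid, voxel_size) {
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "double_distance_map")
}

#' @export
#' @method print binary_volume
print.binary_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %.3g um, porosity %.3f\n",
              d[1], d[2], d[3], x$voxel_size, porosity(x)))
  invisible(x)
}

#' @export
#' @method print double_distance_map
print.double_distance_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<double_distance_map> %d x %d x %d voxels @ %.3g um, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.binary_volume <- function(x) dim(x$grid)

#' @export
dim.double_distance_map <- function(x) dim(x$grid)

#' @export
#' @method as.array binary_volume
as.array.binary_volume <- function(x, ...) x$grid

#' @export
#' @method as.array double_distance_map
as.array.double_distance_map <- function(x, ...) x$grid

# Euclidean distance (voxel units) from every TRUE voxel to the nearest FALSE
# voxel centre; 0 on FALSE voxels. Inf when no FALSE voxel exists.
edt <- function(mask) {
  d <- dim(mask)
  array(sqrt(cpp_edt_sq(as.logical(mask), as.integer(d))), dim = d)
}

solid_grid <- function(x) {
  if (inherits(x, "binary_volume")) x$grid
  else if (is.array(x) && length(dim(x)) == 3L) {
    if (is.logical(x)) x else array(x > 1, dim = dim(x))
  } else stop("expected a binary_volume or 3D array", call. = FALSE)
}

#' Pore volume fraction
#'
#' @param x A [binary_volume()] (or a logical 3D array with `TRUE` = solid).
#' @return Fraction of voxels in the pore phase, in `[0, 1]`.
#' @export
porosity <- function(x) {
  g <- if (inherits(x, "binary_volume")) x$grid else x
  mean(!g)
}

# Count of solid--pore face pairs along the three axes.
count_interface_faces <- function(g) {
  n <- dim(g)
  f <- 0L
  if (n[1] > 1) f <- f + sum(g[-1, , , drop = FALSE] != g[-n[1], , , drop = FALSE])
  if (n[2] > 1) f <- f + sum(g[, -1, , drop = FALSE] != g[, -n[2], , drop = FALSE])
  if (n[3] > 1) f <- f + sum(g[, , -1, drop = FALSE] != g[, , -n[3], drop = FALSE])
  f
}

#' Specific surface area by face counting
#'
#' Interface area between solid and pore phases per unit total volume,
#' estimated by counting voxel faces shared by a solid and a pore voxel.
#'
#' @param x A [binary_volume()].
#' @return Specific surface in 1/mm.
#' @export
specific_surface <- function(x) {
  g <- x$grid
  a_mm <- x$voxel_size / 1000
  count_interface_faces(g) / (length(g) * a_mm)
}

#' Maximum pore diameter
#'
#' Diameter of the largest sphere inscribed in the pore phase: twice the
#' maximum over pore voxels of the Euclidean distance to the nearest solid
#' voxel. An all-solid volume returns 0; an all-pore volume returns the
#' inscribed diameter of the bounding box.
#'
#' @param x A [binary_volume()].
#' @return Diameter in micrometres.
#' @export
max_pore_diameter <- function(x) {
  g <- x$grid
  if (all(g)) return(0)
  if (!any(g)) return(min(dim(g)) * x$voxel_size)
  2 * max(edt(!g)) * x$voxel_size
}
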