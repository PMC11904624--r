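#' Geometric transformations for dataset diversification
#'
#' Applies one of seven fixed transformations to a double distance map. The
#' family pairs small rotations (plus or minus 8 degrees, a small angle that
#' keeps the post-rotation crop modest) about each array axis with grayscale
#' morphological operators using a spherical structuring element of diameter
#' 3 voxels:
#'
#' | `i` | rotation            | morphology |
#' |-----|---------------------|------------|
#' | 1   | none                | none       |
#' | 2   | +8 deg about axis 3 | none       |
#' | 3   | -8 deg about axis 3 | none       |
#' | 4   | +8 deg about axis 2 | opening    |
#' | 5   | -8 deg about axis 2 | closing    |
#' | 6   | +8 deg about axis 1 | erosion    |
#' | 7   | -8 deg about axis 1 | dilation   |
#'
#' Morphology is applied first (on the grayscale map, so erosion shrinks the
#' bright solid phase), then the rotation with trilinear interpolation. The
#' rotated volume is cropped to the largest axis-aligned box containing only
#' valid (non-extrapolated) voxels. Finally the distance values are scaled by
#' `scale` about the interface level 1 (so `I` becomes
#' `(I - 1) * scale + 1`), shifted by `shift` and clipped to `[0, 2]`; in the
#' dataset builder those two amounts are drawn once per transformed volume,
#' uniformly from `[0.9, 1.1]` and `[-0.1, 0.1]`.
#'
#' @param map A `double_distance_map`.
#' @param i Transform index in `1:7`; `i = 1` is the identity.
#' @param shift Additive intensity shift (default 0).
#' @param scale Multiplicative intensity scale (default 1).
#' @return A transformed (possibly smaller, due to validity cropping)
#'   `double_distance_map`.
#' @export
apply_transform <- function(map, i, shift = 0, scale = 1) {
  stopifnot(inherits(map, "double_distance_map"))
  if (!(length(i) == 1L && i %in% 1:7))
    stop("transform index `i` must be a single integer in 1..7", call. = FALSE)
  spec <- transform_table[[i]]
  g <- map$grid
  d <- dim(g)
  if (!is.null(spec$morph)) {
    g <- switch(spec$morph,
      erosion  = array(cpp_morph_gray(as.numeric(g), as.integer(d), 0L), dim = d),
      dilation = array(cpp_morph_gray(as.numeric(g), as.integer(d), 1L), dim = d),
      open = {
        e <- cpp_morph_gray(as.numeric(g), as.integer(d), 0L)
        array(cpp_morph_gray(e, as.integer(d), 1L), dim = d)
      },
      close = {
        dl <- cpp_morph_gray(as.numeric(g), as.integer(d), 1L)
        array(cpp_morph_gray(dl, as.integer(d), 0L), dim = d)
      })
  }
  if (!is.null(spec$rot_axis)) {
    r <- array(cpp_rotate_axis(as.numeric(g), as.integer(d),
                               as.integer(spec$rot_axis), spec$angle), dim = d)
    g <- crop_valid(r, spec$rot_axis)
  }
  # scale acts on the distance values themselves, i.e. on (I - 1), so the
  # phase interface at 1 is preserved; shift then moves the interface.
  g <- pmin(pmax((g - 1) * scale + 1 + shift, 0), 2)
  g <- array(g, dim = dim(g))
  new_double_distance_map(g, map$voxel_size)
}

transform_table <- list(
  list(rot_axis = NULL, angle = 0, morph = NULL),
  list(rot_axis = 3, angle = 8, morph = NULL),
  list(rot_axis = 3, angle = -8, morph = NULL),
  list(rot_axis = 2, angle = 8, morph = "open"),
  list(rot_axis = 2, angle = -8, morph = "close"),
  list(rot_axis = 1, angle = 8, morph = "erosion"),
  list(rot_axis = 1, angle = -8, morph = "dilation")
)

# Crop a rotated array (NA outside the source footprint) to the largest
# axis-aligned all-valid box. Validity only varies in the rotation plane, so
# the search is 2D: for each row of the plane take the contiguous valid
# column range, then maximize the inscribed rectangle area over row ranges.
crop_valid <- function(r, rot_axis) {
  d <- dim(r)
  plane_axes <- setdiff(1:3, rot_axis)
  slice <- switch(rot_axis,
                  `1` = r[1, , ],
                  `2` = r[, 1, ],
                  `3` = r[, , 1])
  valid <- !is.na(slice)
  nu <- nrow(valid); nv <- ncol(valid)
  lo <- integer(nu); hi <- integer(nu)
  for (u in seq_len(nu)) {
    w <- which(valid[u, ])
    if (length(w) == 0L) { lo[u] <- NA_integer_; hi[u] <- NA_integer_ }
    else { lo[u] <- min(w); hi[u] <- max(w) }
  }
  best <- c(0, 1, 1, 1, 1) # area, u1, u2, v1, v2
  for (u1 in seq_len(nu)) {
    if (is.na(lo[u1])) next
    vlo <- lo[u1]; vhi <- hi[u1]
    for (u2 in u1:nu) {
      if (is.na(lo[u2])) break
      vlo <- max(vlo, lo[u2]); vhi <- min(vhi, hi[u2])
      if (vhi < vlo) break
      area <- (u2 - u1 + 1) * (vhi - vlo + 1)
      if (area > best[1]) best <- c(area, u1, u2, vlo, vhi)
    }
  }
  if (best[1] == 0) stop("rotation left no valid region to crop", call. = FALSE)
  idx <- vector("list", 3)
  idx[[rot_axis]] <- seq_len(d[rot_axis])
  idx[[plane_axes[1]]] <- best[2]:best[3]
  idx[[plane_axes[2]]] <- best[4]:best[5]
  out <- r[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  stopifnot(!anyNA(out))
  out
}
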