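#' Read and write volumes on disk
#'
#' Binary volumes are stored as multi-page TIFF, one z-slice per page, 8-bit
#' (0 = pore, 255 = solid). Double distance maps are stored as raw
#' little-endian 32-bit float voxels in x-fastest order; integer-sampled
#' TIFF cannot hold them losslessly. Both carry a JSON sidecar
#' (`<path>.json`) with the value type, shape and voxel size, which
#' [read_volume()] uses to reconstruct the object.
#'
#' @param vol A [binary_volume()] or `double_distance_map`.
#' @param path Output TIFF path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   the reconstructed object. Reading a file without a sidecar assumes a
#'   binary volume at the default 6.25 um voxel size, with a warning.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_volume")) {
    pages <- lapply(seq_len(dim(vol$grid)[3]),
                    function(k) matrix(as.numeric(vol$grid[, , k]),
                                       nrow = dim(vol$grid)[1]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    meta <- list(type = "binary", voxel_size_um = vol$voxel_size,
                 shape = dim(vol$grid), encoding = "8-bit, 0=pore, 255=solid")
  } else if (inherits(vol, "double_distance_map")) {
    con <- file(path, "wb")
    writeBin(as.numeric(vol$grid), con, size = 4L, endian = "little")
    close(con)
    meta <- list(type = "map", voxel_size_um = vol$voxel_size,
                 shape = dim(vol$grid),
                 encoding = "raw float32, little-endian, x fastest")
  } else stop("`vol` must be a binary_volume or double_distance_map", call. = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (!is.null(meta) && identical(meta$type, "map")) {
    shape <- as.integer(meta$shape)
    vals <- readBin(path, what = "numeric", n = prod(shape), size = 4L,
                    endian = "little")
    if (length(vals) != prod(shape))
      stop(sprintf("sidecar shape %s does not match raw file length %d",
                   paste(shape, collapse = "x"), length(vals)), call. = FALSE)
    return(new_double_distance_map(array(vals, dim = shape),
                                   meta$voxel_size_um))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (!is.null(meta)) {
    if (!is.null(meta$shape) && !identical(as.integer(meta$shape), dim(arr)))
      stop(sprintf("sidecar shape %s does not match TIFF pages %s",
                   paste(meta$shape, collapse = "x"),
                   paste(dim(arr), collapse = "x")), call. = FALSE)
    return(binary_volume(array(arr > 0.5, dim = dim(arr)),
                         voxel_size = meta$voxel_size_um))
  }
  warning("no JSON sidecar found; assuming binary volume at 6.25 um voxel size")
  binary_volume(array(arr > 0.5, dim = dim(arr)), voxel_size = 6.25)
}
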