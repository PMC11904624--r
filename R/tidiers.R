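#' Tidy a pore network into per-pore or per-throat tibbles
#'
#' @param x A `pore_network`.
#' @param what `"pores"` (default) or `"throats"`.
#' @param ... Unused.
#' @return A tibble of pores (id, centroid, radius, volume, connectivity) or
#'   throats (pore pair, radius, length).
#' @export
tidy.pore_network <- function(x, what = c("pores", "throats"), ...) {
  what <- match.arg(what)
  if (what == "pores") x$pores else x$throats
}

#' One-row summary of a pore network
#'
#' @param x A `pore_network`.
#' @param ... Unused.
#' @return A tibble with pore/throat counts and mean geometric properties.
#' @export
glance.pore_network <- function(x, ...) {
  tibble::tibble(n_pores = nrow(x$pores), n_throats = nrow(x$throats),
                 mean_pore_radius_um = mean(x$pores$radius_um),
                 mean_throat_radius_um = if (nrow(x$throats))
                   mean(x$throats$radius_um) else NA_real_,
                 mean_connectivity = mean(x$pores$connectivity),
                 voxel_size_um = x$voxel_size)
}

#' One-row summary of a reconstruction
#'
#' @param x A `fibro_recon`.
#' @param ... Unused.
#' @return A tibble with output porosity, placement count, the matching
#'   quality diagnostic (fraction of constrained placements with error below
#'   0.2) and the seed.
#' @export
glance.fibro_recon <- function(x, ...) {
  tibble::tibble(porosity = porosity(x$volume),
                 n_placements = nrow(x$matching),
                 fraction_matched = x$fraction_matched,
                 dataset_size = x$dataset_size,
                 seed = x$config$seed)
}

#' Per-placement matching record of a reconstruction
#'
#' @param x A `fibro_recon`.
#' @param ... Unused.
#' @return The per-placement tibble: corner, placement order, chosen patch
#'   index and matching error (`NA` for unconstrained first placements).
#' @export
tidy.fibro_recon <- function(x, ...) x$matching

slice_df <- function(m, value_name = "value") {
  tibble::tibble(x = rep(seq_len(nrow(m)), ncol(m)),
                 y = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
}

#' Plot the mid-slice of a binary volume
#'
#' @param object A [binary_volume()].
#' @param slice Index of the z-slice (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice (solid dark, pore light).
#' @export
autoplot.binary_volume <- function(object, slice = NULL, ...) {
  d <- dim(object$grid)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- slice_df(object$grid[, , slice] * 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "grey20"),
                               labels = c("pore", "solid"), name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", slice), x = NULL, y = NULL)
}

#' Plot the mid-slice of a double distance map
#'
#' @param object A `double_distance_map`.
#' @param slice Index of the z-slice (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster with the interface at value 1.
#' @export
autoplot.double_distance_map <- function(object, slice = NULL, ...) {
  d <- dim(object$grid)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- slice_df(object$grid[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "white", mid = "steelblue",
                                  high = "black", name = "I") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", slice), x = NULL, y = NULL)
}

#' Plot a patch dataset in feature space
#'
#' Scatter of the normalized feature coordinates alpha (porosity) and gamma
#' (maximum pore size), coloured by beta (specific surface).
#'
#' @param object A `patch_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.patch_dataset <- function(object, ...) {
  ggplot2::ggplot(object$info,
                  ggplot2::aes(x = .data$alpha, y = .data$gamma,
                               colour = .data$beta)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = expression(beta)) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(alpha ~ "(porosity)"),
                  y = expression(gamma ~ "(max pore size)"))
}

#' Plot a porosity or property map
#'
#' @param object A `porosity_map` or `property_maps` object.
#' @param which For `property_maps`: one of `"KL"`, `"KT"`, `"En"`.
#' @param ... Unused.
#' @return A ggplot raster; missing (masked) pixels are blank.
#' @export
autoplot.porosity_map <- function(object, ...) {
  df <- slice_df(object$porosity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "porosity", na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname autoplot.porosity_map
#' @export
autoplot.property_maps <- function(object, which = c("KL", "KT", "En"), ...) {
  which <- match.arg(which)
  df <- slice_df(object[[which]])
  unit <- if (which == "En") "" else " (Darcy)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(which, unit), na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
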