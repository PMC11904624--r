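#' Extract a pore network by marker-based watershed
#'
#' Partitions the pore space of a binary volume into individual pores and the
#' throats connecting them. The pipeline is the standard marker-based
#' watershed formulation for granular/fibrous media: Euclidean distance
#' transform of the pore phase, light Gaussian pre-smoothing
#' (`smooth_sigma`), h-maxima suppression (morphological reconstruction with
#' height `h_merge`, merging maxima that differ by less than `h_merge`
#' voxels) to obtain one marker per pore, then priority-flood watershed of
#' the negated distance map seeded at those markers. Throats are the shared
#' boundaries between adjacent watershed regions.
#'
#' Radii are inscribed-sphere radii: a pore's radius is the maximum pore
#' distance transform over its region; a throat's radius is the largest
#' distance-transform value on the shared boundary, taken conservatively as
#' `min` over each boundary voxel pair so that a throat is never wider than
#' either of its pores. Throat length is the centre-to-centre distance of the
#' two pores.
#'
#' @param volume A [binary_volume()] with a non-empty pore phase.
#' @param h_merge H-maxima suppression depth in voxels (default 1).
#' @param smooth_sigma Gaussian pre-smoothing of the distance map in voxels
#'   (default 0.4).
#' @return A `pore_network`: `pores` (tibble: `pore`, `x`, `y`, `z` voxel
#'   centroids, `radius_um`, `volume_um3`, `connectivity`), `throats`
#'   (tibble: `pore1`, `pore2`, `radius_um`, `length_um`), `boundary` (list
#'   of pore id vectors for the six faces `x0, x1, y0, y1, z0, z1`),
#'   `labels` (the watershed label array), `shape` and `voxel_size`.
#' @export
extract_network <- function(volume, h_merge = 1, smooth_sigma = 0.4) {
  stopifnot(inherits(volume, "binary_volume"))
  g <- volume$grid
  pore <- !g
  if (!any(pore)) stop("no pore phase present", call. = FALSE)
  d <- dim(g)
  a <- volume$voxel_size
  if (any(g)) {
    dt <- edt(pore)
  } else {
    # all-pore volume: measure depth from the volume boundary instead
    pad <- array(FALSE, dim = d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- TRUE
    dt <- edt(pad)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  }
  dts <- gauss_smooth(dt, smooth_sigma)
  dts[!pore] <- 0
  rec <- array(cpp_grayrec_dilate(as.numeric(dts - h_merge), as.numeric(dts),
                                  as.integer(d)), dim = d)
  markers <- cpp_regional_maxima(as.numeric(rec), as.logical(pore), as.integer(d))
  lab <- array(cpp_watershed(as.numeric(-dts), markers, as.logical(pore),
                             as.integer(d)), dim = d)
  npore <- max(lab)
  stopifnot(npore >= 1L, all(lab[pore] > 0L))

  idx <- which(pore)
  labv <- lab[idx]
  coord <- arrayInd(idx, d)
  cx <- tapply(coord[, 1], labv, mean)
  cy <- tapply(coord[, 2], labv, mean)
  cz <- tapply(coord[, 3], labv, mean)
  counts <- tabulate(labv, nbins = npore)
  rad <- tapply(dt[idx], labv, max)
  pores <- tibble::tibble(pore = as.integer(names(cx)),
                          x = as.numeric(cx), y = as.numeric(cy),
                          z = as.numeric(cz),
                          radius_um = as.numeric(rad) * a,
                          volume_um3 = counts[as.integer(names(cx))] * a^3)
  pores <- pores[order(pores$pore), ]

  throats <- find_throats(lab, dt, pores, a)
  conn <- integer(npore)
  if (nrow(throats)) {
    tt <- table(factor(c(throats$pore1, throats$pore2), levels = seq_len(npore)))
    conn <- as.integer(tt)
  }
  pores$connectivity <- conn

  face_ids <- function(slice) sort(unique(slice[slice > 0L]))
  boundary <- list(x0 = face_ids(lab[1, , ]), x1 = face_ids(lab[d[1], , ]),
                   y0 = face_ids(lab[, 1, ]), y1 = face_ids(lab[, d[2], ]),
                   z0 = face_ids(lab[, , 1]), z1 = face_ids(lab[, , d[3]]))
  structure(list(pores = pores, throats = throats, boundary = boundary,
                 labels = lab, shape = d, voxel_size = a),
            class = "pore_network")
}

# Shared-boundary throats between 6-adjacent voxels of different labels.
find_throats <- function(lab, dt, pores, a) {
  d <- dim(lab)
  pair_l1 <- integer(0); pair_l2 <- integer(0); pair_r <- numeric(0)
  collect <- function(A, B, dA, dB) {
    sel <- A > 0L & B > 0L & A != B
    if (!any(sel)) return()
    l1 <- pmin(A[sel], B[sel]); l2 <- pmax(A[sel], B[sel])
    r <- pmin(dA[sel], dB[sel])
    pair_l1 <<- c(pair_l1, l1); pair_l2 <<- c(pair_l2, l2); pair_r <<- c(pair_r, r)
  }
  if (d[1] > 1) collect(lab[-d[1], , ], lab[-1, , ], dt[-d[1], , ], dt[-1, , ])
  if (d[2] > 1) collect(lab[, -d[2], ], lab[, -1, ], dt[, -d[2], ], dt[, -1, ])
  if (d[3] > 1) collect(lab[, , -d[3]], lab[, , -1], dt[, , -d[3]], dt[, , -1])
  if (!length(pair_l1))
    return(tibble::tibble(pore1 = integer(0), pore2 = integer(0),
                          radius_um = numeric(0), length_um = numeric(0)))
  key <- paste(pair_l1, pair_l2, sep = "-")
  agg <- tapply(pair_r, key, max)
  ks <- strsplit(names(agg), "-", fixed = TRUE)
  p1 <- vapply(ks, function(k) as.integer(k[1]), integer(1))
  p2 <- vapply(ks, function(k) as.integer(k[2]), integer(1))
  len <- sqrt((pores$x[p1] - pores$x[p2])^2 +
              (pores$y[p1] - pores$y[p2])^2 +
              (pores$z[p1] - pores$z[p2])^2) * a
  out <- tibble::tibble(pore1 = p1, pore2 = p2,
                        radius_um = as.numeric(agg) * a,
                        length_um = pmax(len, a / 2))
  out[order(out$pore1, out$pore2), ]
}

#' @export
#' @method print pore_network
print.pore_network <- function(x, ...) {
  cat(sprintf("<pore_network> %d pores, %d throats, %d x %d x %d voxels @ %.3g um\n",
              nrow(x$pores), nrow(x$throats), x$shape[1], x$shape[2],
              x$shape[3], x$voxel_size))
  invisible(x)
}

DARCY_M2 <- 9.869e-13

#' Directional Darcy permeability of a pore network
#'
#' Solves incompressible Hagen-Poiseuille network flow: each throat carries a
#' conductance \eqn{g = \pi r^4 / (8 \mu l)}, boundary pores connect to
#' virtual inlet/outlet face reservoirs through half-throats of the pore's
#' own radius and its centre-to-face distance, and mass conservation at every
#' pore yields a sparse linear system for the pore pressures under a unit
#' pressure drop. The volumetric flux `Q` then gives the Darcy permeability
#' `K = Q mu L / (A dP)`, reported in Darcy (1 Darcy = 9.869e-13 m^2). The
#' fluid viscosity cancels out of `K`; it is exposed only for completeness.
#'
#' @param network A `pore_network`.
#' @param axis Flow axis: `"x"`, `"y"` or `"z"` (or 1..3).
#' @param fluid_viscosity Dynamic viscosity in Pa s (default 1e-3, water).
#' @return Permeability in Darcy. When no inlet-to-outlet path exists the
#'   value is 0 with attribute `non_percolating = TRUE`. The maximum relative
#'   mass-balance residual of the solve is attached as attribute
#'   `max_rel_residual`.
#' @export
network_permeability <- function(network, axis = "z", fluid_viscosity = 1e-3) {
  stopifnot(inherits(network, "pore_network"))
  ax <- if (is.character(axis)) match(tolower(axis), c("x", "y", "z"))
        else as.integer(axis)
  if (is.na(ax) || !(ax %in% 1:3)) stop("`axis` must be x, y, z or 1..3", call. = FALSE)
  a_m <- network$voxel_size * 1e-6
  d <- network$shape
  mu <- fluid_viscosity
  inlet <- network$boundary[[2L * ax - 1L]]
  outlet <- network$boundary[[2L * ax]]
  zero <- structure(0, non_percolating = TRUE, max_rel_residual = 0)
  if (!length(inlet) || !length(outlet)) return(zero)

  npore <- nrow(network$pores)
  thr <- network$throats
  # percolation check on the pore graph with virtual face nodes
  vin <- npore + 1L; vout <- npore + 2L
  edges <- rbind(cbind(thr$pore1, thr$pore2),
                 cbind(rep(vin, length(inlet)), inlet),
                 cbind(rep(vout, length(outlet)), outlet))
  gr <- igraph::graph_from_edgelist(apply(edges, 2, as.character), directed = FALSE)
  if (!igraph::are_adjacent(gr, as.character(vin), as.character(vout)) &&
      is.infinite(igraph::distances(gr, as.character(vin), as.character(vout))[1, 1]))
    return(zero)

  coords <- as.matrix(network$pores[, c("x", "y", "z")])
  centre_d <- function(ids, face) {
    pos <- coords[ids, ax]
    dd <- if (face == 0L) pos - 0.5 else (d[ax] + 0.5) - pos
    pmax(dd, 0.5) * a_m
  }
  g_th <- pi * (thr$radius_um * 1e-6)^4 / (8 * mu * thr$length_um * 1e-6)
  r_in <- network$pores$radius_um[inlet] * 1e-6
  g_in <- pi * r_in^4 / (8 * mu * centre_d(inlet, 0L))
  r_out <- network$pores$radius_um[outlet] * 1e-6
  g_out <- pi * r_out^4 / (8 * mu * centre_d(outlet, 1L))

  # keep only pores connected to the inlet/outlet component
  comp <- igraph::components(gr)
  main_id <- comp$membership[as.character(vin)]
  keep_named <- names(comp$membership)[comp$membership == main_id]
  keep <- sort(as.integer(setdiff(keep_named, as.character(c(vin, vout)))))
  if (!length(keep)) return(zero)
  remap <- integer(npore)
  remap[keep] <- seq_along(keep)
  nk <- length(keep)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(nk)
  b <- numeric(nk)
  tsel <- remap[thr$pore1] > 0L & remap[thr$pore2] > 0L
  if (any(tsel)) {
    p1 <- remap[thr$pore1[tsel]]; p2 <- remap[thr$pore2[tsel]]
    gt <- g_th[tsel]
    ii <- c(ii, p1, p2); jj <- c(jj, p2, p1); vv <- c(vv, -gt, -gt)
    for (k in seq_along(p1)) {
      diag_acc[p1[k]] <- diag_acc[p1[k]] + gt[k]
      diag_acc[p2[k]] <- diag_acc[p2[k]] + gt[k]
    }
  }
  dP <- 1
  isel <- remap[inlet] > 0L
  for (k in which(isel)) {
    p <- remap[inlet[k]]
    diag_acc[p] <- diag_acc[p] + g_in[k]
    b[p] <- b[p] + g_in[k] * dP
  }
  osel <- remap[outlet] > 0L
  for (k in which(osel)) {
    p <- remap[outlet[k]]
    diag_acc[p] <- diag_acc[p] + g_out[k]
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nk)), j = c(jj, seq_len(nk)),
                            x = c(vv, diag_acc), dims = c(nk, nk))
  p <- as.numeric(Matrix::solve(A, b))
  resid <- as.numeric(A %*% p - b)
  scale <- max(abs(b), max(diag_acc) * max(abs(p)))
  max_rel_residual <- if (scale > 0) max(abs(resid)) / scale else 0

  Q <- sum(g_in[isel] * (dP - p[remap[inlet[isel]]]))
  L <- d[ax] * a_m
  A_cs <- prod(d[-ax]) * a_m^2
  K_m2 <- Q * mu * L / (A_cs * dP)
  structure(K_m2 / DARCY_M2, non_percolating = FALSE,
            max_rel_residual = max_rel_residual)
}

#' Morphological and hydraulic summary of a volume/network pair
#'
#' Computes the standard property panel for a fibrous porous volume:
#' volume-weighted mean pore radius (arithmetic available via
#' `pore_radius_stat`), mean throat radius, mean pore connectivity
#' (coordination number), porosity, specific surface area and the
#' directional Darcy permeabilities along the three axes together with their
#' arithmetic mean, an orientation-independent average flowability.
#'
#' @param volume A [binary_volume()].
#' @param network The matching `pore_network` (computed from `volume` with
#'   [extract_network()] if omitted).
#' @param pore_radius_stat `"volume_weighted"` (default) or `"arithmetic"`.
#' @return A one-row tibble with columns `porosity`, `specific_surface_mm`,
#'   `mean_pore_radius_um`, `mean_throat_radius_um`, `mean_connectivity`,
#'   `K_x`, `K_y`, `K_z` and `K_mean` (Darcy).
#' @export
morphology_summary <- function(volume, network = NULL,
                               pore_radius_stat = c("volume_weighted", "arithmetic")) {
  stopifnot(inherits(volume, "binary_volume"))
  pore_radius_stat <- match.arg(pore_radius_stat)
  if (is.null(network)) network <- extract_network(volume)
  stopifnot(inherits(network, "pore_network"))
  pr <- if (pore_radius_stat == "volume_weighted")
    sum(network$pores$radius_um * network$pores$volume_um3) / sum(network$pores$volume_um3)
  else mean(network$pores$radius_um)
  Ks <- vapply(1:3, function(ax) as.numeric(network_permeability(network, ax)),
               numeric(1))
  tibble::tibble(porosity = porosity(volume),
                 specific_surface_mm = specific_surface(volume),
                 mean_pore_radius_um = pr,
                 mean_throat_radius_um = if (nrow(network$throats))
                   mean(network$throats$radius_um) else 0,
                 mean_connectivity = mean(network$pores$connectivity),
                 K_x = Ks[1], K_y = Ks[2], K_z = Ks[3], K_mean = mean(Ks))
}
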