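# Fixtures built in code: constructed geometries with known analytic
# properties, plus small seeded random volumes.

random_volume <- function(dims, p_solid = 0.5, seed = 1, voxel_size = 6.25) {
  g <- withr::with_seed(seed, array(runif(prod(dims)) < p_solid, dim = dims))
  # guarantee both phases
  if (all(g)) g[1] <- FALSE
  if (!any(g)) g[1] <- TRUE
  binary_volume(g, voxel_size = voxel_size)
}

# single spherical cavity of radius r (voxels) inside solid
sphere_cavity_volume <- function(n = 24, r = 5, voxel_size = 6.25) {
  cc <- (n + 1) / 2
  idx <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  g <- array(TRUE, dim = c(n, n, n))
  g[(idx$x - cc)^2 + (idx$y - cc)^2 + (idx$z - cc)^2 <= r^2] <- FALSE
  binary_volume(g, voxel_size = voxel_size)
}

# two spherical cavities joined by a narrow cylindrical neck along x
two_sphere_volume <- function(r_sphere = 6, r_neck = 2, voxel_size = 6.25) {
  d <- c(40, 20, 20)
  idx <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  g <- array(TRUE, dim = d)
  pore <- (idx$x - 10)^2 + (idx$y - 10)^2 + (idx$z - 10)^2 <= r_sphere^2 |
          (idx$x - 30)^2 + (idx$y - 10)^2 + (idx$z - 10)^2 <= r_sphere^2 |
          (idx$x >= 10 & idx$x <= 30 &
             (idx$y - 10)^2 + (idx$z - 10)^2 <= r_neck^2)
  g[pore] <- FALSE
  binary_volume(g, voxel_size = voxel_size)
}

# straight cylindrical channel of radius r along z, centred on a voxel
channel_volume <- function(r = 5, n_xy = 21, n_z = 40, voxel_size = 6.25) {
  cc <- (n_xy + 1) / 2 # integer for odd n_xy
  g <- array(TRUE, dim = c(n_xy, n_xy, n_z))
  sl <- outer(seq_len(n_xy), seq_len(n_xy),
              function(x, y) (x - cc)^2 + (y - cc)^2 <= r^2)
  g[rep(sl, n_z)] <- FALSE
  binary_volume(g, voxel_size = voxel_size)
}

# axis-aligned solid/pore stripes (period 2w along x)
striped_volume <- function(dims = c(32, 32, 32), w = 4, voxel_size = 6.25) {
  x <- rep(seq_len(dims[1]), times = dims[2] * dims[3])
  g <- array(((x - 1) %/% w) %% 2 == 0, dim = dims)
  binary_volume(g, voxel_size = voxel_size)
}

small_phantom <- function(seed = 3, shape = c(48, 48, 48), ...) {
  generate_fibrous_volume(phantom_spec(shape = shape, seed = seed, ...))
}

expect_rel_error_lt <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
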