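test_that("a single spherical cavity yields one pore and no throats", {
  v <- sphere_cavity_volume(n = 24, r = 5)
  nw <- extract_network(v)
  expect_identical(nrow(nw$pores), 1L)
  expect_identical(nrow(nw$throats), 0L)
  expect_lt(abs(nw$pores$radius_um / v$voxel_size - 5), 1)
  expect_identical(nw$pores$connectivity, 0L)
})

test_that("two cavities joined by a narrow neck give two pores and one throat", {
  v <- two_sphere_volume(r_sphere = 6, r_neck = 2)
  nw <- extract_network(v)
  expect_identical(nrow(nw$pores), 2L)
  expect_identical(nrow(nw$throats), 1L)
  expect_lt(abs(nw$throats$radius_um / v$voxel_size - 2), 1)
  expect_true(all(abs(nw$pores$radius_um / v$voxel_size - 6) < 1))
  expect_identical(nw$pores$connectivity, c(1L, 1L))
})

test_that("network invariants hold on phantom extractions", {
  v <- small_phantom(seed = 13, shape = c(40, 40, 40))
  nw <- extract_network(v)
  a <- v$voxel_size
  # watershed partitions the pore phase
  expect_equal(sum(nw$pores$volume_um3), sum(!v$grid) * a^3)
  # connectivity equals incident throat count
  inc <- table(factor(c(nw$throats$pore1, nw$throats$pore2),
                      levels = nw$pores$pore))
  expect_identical(nw$pores$connectivity, as.integer(inc))
  # inscribed geometry: throat no wider than either of its pores
  r_of <- nw$pores$radius_um[order(nw$pores$pore)]
  expect_true(all(nw$throats$radius_um <=
                    pmin(r_of[nw$throats$pore1], r_of[nw$throats$pore2]) + 1e-9))
  # labels cover the pore phase exactly
  expect_true(all(nw$labels[!v$grid] > 0))
  expect_true(all(nw$labels[v$grid] == 0))
})

test_that("single-channel permeability approaches the Hagen-Poiseuille value", {
  r <- 5
  v <- channel_volume(r = r, n_xy = 21, n_z = 40)
  nw <- extract_network(v)
  K <- network_permeability(nw, "z")
  a_m <- v$voxel_size * 1e-6
  K_analytic <- pi * (r * a_m)^4 / (8 * (21 * a_m)^2) / 9.869e-13
  expect_rel_error_lt(as.numeric(K), K_analytic, 0.15)
  expect_false(attr(K, "non_percolating"))
  # viscosity cancels out of the permeability
  K2 <- network_permeability(nw, "z", fluid_viscosity = 3.7e-3)
  expect_equal(as.numeric(K2), as.numeric(K))
})

test_that("parallel identical channels conduct additively", {
  r <- 5
  v1 <- channel_volume(r = r, n_xy = 21, n_z = 40)
  g2 <- array(TRUE, dim = c(42, 21, 40))
  g2[1:21, , ] <- v1$grid
  g2[22:42, , ] <- v1$grid
  v2 <- binary_volume(g2, v1$voxel_size)
  K1 <- as.numeric(network_permeability(extract_network(v1), "z"))
  K2 <- as.numeric(network_permeability(extract_network(v2), "z"))
  # total conductance K*A doubles, so K is unchanged with doubled area
  expect_rel_error_lt(K2 * 2, K1 * 2, 0.01)
  expect_rel_error_lt(K2, K1, 0.01)
})

test_that("non-percolating volumes return zero with a flag", {
  g <- array(TRUE, dim = c(16, 16, 16))
  g[4:12, 4:12, 1:8] <- FALSE # blind pocket open to one face only
  nw <- extract_network(binary_volume(g))
  K <- network_permeability(nw, "z")
  expect_identical(as.numeric(K), 0)
  expect_true(attr(K, "non_percolating"))
})

test_that("interior mass balance is conserved to solver tolerance", {
  v <- small_phantom(seed = 21, shape = c(40, 40, 40))
  nw <- extract_network(v)
  for (ax in c("x", "y", "z")) {
    K <- network_permeability(nw, ax)
    expect_lt(attr(K, "max_rel_residual"), 1e-10)
  }
})

test_that("permeability in physical units scales with the voxel size squared", {
  v <- small_phantom(seed = 23, shape = c(40, 40, 40))
  big <- binary_volume(v$grid, voxel_size = 2 * v$voxel_size)
  K1 <- as.numeric(network_permeability(extract_network(v), "z"))
  K2 <- as.numeric(network_permeability(extract_network(big), "z"))
  expect_gt(K1, 0)
  expect_rel_error_lt(K2, 4 * K1, 1e-6)
})

test_that("mean permeability rises monotonically with phantom porosity", {
  Ks <- vapply(c(0.45, 0.55, 0.65, 0.75), function(p) {
    v <- generate_fibrous_volume(phantom_spec(shape = c(48, 48, 48),
                                              target_porosity = p, seed = 17))
    morphology_summary(v)$K_mean
  }, numeric(1))
  expect_true(all(diff(Ks) > 0))
})

test_that("morphology summary handles degenerate and phantom volumes", {
  allpore <- binary_volume(array(FALSE, dim = c(12, 12, 12)))
  s <- morphology_summary(allpore)
  expect_equal(s$porosity, 1)
  expect_equal(s$specific_surface_mm, 0)
  v <- small_phantom(seed = 2, shape = c(48, 48, 48))
  s2 <- morphology_summary(v)
  expect_lt(abs(s2$porosity - 0.61), 0.03)
  expect_gt(s2$mean_pore_radius_um, 0)
  # volume-weighted vs arithmetic pore radius both available
  s3 <- morphology_summary(v, pore_radius_stat = "arithmetic")
  expect_false(identical(s2$mean_pore_radius_um, s3$mean_pore_radius_um))
})

test_that("aligned phantoms conduct better along the fibre axis", {
  sp <- phantom_spec(shape = c(64, 64, 64), orientation_jitter = 0,
                     target_porosity = 0.61, seed = 3)
  s <- morphology_summary(generate_fibrous_volume(sp))
  expect_gt(s$K_z, mean(c(s$K_x, s$K_y)))
})
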