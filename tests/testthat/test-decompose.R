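test_that("image-domain decomposition inverts the forward composition", {
  m <- fixture_model()
  A <- decomposition_matrix(m)
  vol <- fixture_small_phantom()
  mono <- simulate_monoenergetic(vol, m)
  mat <- decompose_image_domain(mono, A)
  denom_w <- pmax(abs(vol$water_density), 1e-9)
  denom_b <- pmax(abs(vol$hydroxyapatite_density), 1e-9)
  expect_lt(max(abs(mat$water_density - vol$water_density) / denom_w), 1e-8)
  expect_lt(max(abs(mat$hydroxyapatite_density -
                      vol$hydroxyapatite_density) / denom_b), 1e-8)
})

test_that("zero attenuation maps to zero density and pure water to zero bone", {
  m <- fixture_model()
  A <- decomposition_matrix(m)
  sp <- structure(list(mu_low = array(0, c(4, 4, 2)),
                       mu_high = array(0, c(4, 4, 2)),
                       energies_kev = c(50, 200),
                       voxel_spacing = c(1, 1, 1)),
                  class = "spectral_volume_pair")
  mat <- decompose_image_domain(sp, A)
  expect_true(all(mat$water_density == 0))
  expect_true(all(mat$hydroxyapatite_density == 0))

  # a 1 g/mL water voxel produces the water attenuation exactly; the bone
  # channel must vanish to numerical tolerance
  sp$mu_low[] <- mass_attenuation(m, "water", 50)
  sp$mu_high[] <- mass_attenuation(m, "water", 200)
  mat <- decompose_image_domain(sp, A)
  expect_equal(max(abs(mat$water_density - 1)), 0, tolerance = 1e-10)
  expect_lt(max(abs(mat$hydroxyapatite_density)), 1e-6)
})

test_that("decomposition is linear and matches a generic per-voxel solver", {
  m <- fixture_model()
  A <- decomposition_matrix(m)
  mk <- function(seed) {
    withr::with_seed(seed, {
      structure(list(mu_low = array(runif(16 * 16, 0.1, 0.5), c(16, 16, 1)),
                     mu_high = array(runif(16 * 16, 0.05, 0.3),
                                     c(16, 16, 1)),
                     energies_kev = c(50, 200), voxel_spacing = c(1, 1, 1)),
                class = "spectral_volume_pair")
    })
  }
  X <- mk(1); Y <- mk(2)
  aXbY <- X
  aXbY$mu_low <- 2 * X$mu_low + 3 * Y$mu_low
  aXbY$mu_high <- 2 * X$mu_high + 3 * Y$mu_high
  dx <- decompose_image_domain(X, A)
  dy <- decompose_image_domain(Y, A)
  dxy <- decompose_image_domain(aXbY, A)
  expect_equal(dxy$water_density, 2 * dx$water_density + 3 * dy$water_density,
               tolerance = 1e-12)
  expect_equal(dxy$hydroxyapatite_density,
               2 * dx$hydroxyapatite_density + 3 * dy$hydroxyapatite_density,
               tolerance = 1e-12)
  # independent generic solver, voxel by voxel
  for (i in sample(1:16, 4)) for (j in sample(1:16, 4)) {
    ref <- unname(solve(A$entries, c(X$mu_low[i, j, 1], X$mu_high[i, j, 1])))
    expect_equal(dx$water_density[i, j, 1], ref[1], tolerance = 1e-12)
    expect_equal(dx$hydroxyapatite_density[i, j, 1], ref[2] * 1000,
                 tolerance = 1e-9)
  }
})

test_that("projection-domain decomposition recovers areal densities", {
  m <- fixture_model()
  # zero EPL -> zero aBMD
  z <- spectral_projection_pair(matrix(0, 8, 8), matrix(0, 8, 8), c(1, 1))
  expect_true(all(epl_to_abmd(z, m) == 0))

  # pure water ray: photoelectric and Compton EPL both equal the water
  # thickness, aBMD vanishes
  w10 <- spectral_projection_pair(matrix(10, 8, 8), matrix(10, 8, 8),
                                  c(1, 1))
  expect_lt(max(abs(epl_to_abmd(w10, m))), 1e-6)

  # slab of 150 mg/mL hydroxyapatite, 3 cm thick, inside water: aBMD is
  # 0.45 g/cm^2 (analytic areal density) through the noiseless simulator
  cf <- m$basis_coefficients
  W <- 10; B <- 0.150 * 3
  P <- cf["photoelectric", "water"] * W + cf["photoelectric", "bone"] * B
  C <- cf["compton", "water"] * W + cf["compton", "bone"] * B
  pr <- spectral_projection_pair(
    matrix(P / cf["photoelectric", "water"], 4, 4),
    matrix(C / cf["compton", "water"], 4, 4), c(1, 1))
  ab <- epl_to_abmd(pr, m)
  expect_equal(mean(ab), 0.45, tolerance = 0.01)
})

test_that("virtual monoenergetic projections reconstruct channel integrals", {
  m <- fixture_model()
  vol <- fixture_small_phantom()
  geo <- fixture_geometry()
  acq <- scout_acquisition(fluence_per_pixel = Inf)
  sc <- simulate_scout(vol, geo, acq, m)
  # at a channel energy the synthesized projection equals the simulated
  # channel line integral
  e1 <- acq$channel_energies[1]
  L1 <- virtual_monoenergetic_projection(sc, e1, m)
  ad <- sdexa:::project_volumes(list(vol$water_density,
                                     vol$hydroxyapatite_density / 1000),
                                vol$voxel_spacing, geo)
  L1_direct <- mass_attenuation(m, "water", e1) * ad[[1]] / 10 +
    mass_attenuation(m, "hydroxyapatite", e1) * ad[[2]] / 10
  expect_lt(max(abs(L1 - L1_direct)) / max(L1_direct), 1e-6)

  # zero maps synthesize to zero at any energy
  z <- spectral_projection_pair(matrix(0, 4, 4), matrix(0, 4, 4), c(1, 1))
  expect_true(all(virtual_monoenergetic_projection(z, 80, m) == 0))
  expect_error(virtual_monoenergetic_projection(z, 250, m), "keV")

  # water-only ray: line integral strictly decreasing over 40-150 keV
  w <- spectral_projection_pair(matrix(10, 2, 2), matrix(10, 2, 2), c(1, 1))
  sweep_L <- vapply(seq(40, 150, by = 5), function(e)
    virtual_monoenergetic_projection(w, e, m)[1, 1], numeric(1))
  expect_true(all(diff(sweep_L) < 0))
})
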