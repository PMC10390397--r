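make_noise_pair <- function(n = 64, sd_p = 1, sd_c = 1, rho = -1,
                            mean_p = 10, mean_c = 10, seed = 1) {
  withr::with_seed(seed, {
    z1 <- matrix(rnorm(n * n), n, n)
    z2 <- matrix(rnorm(n * n), n, n)
    p <- mean_p + sd_p * z1
    c_ <- mean_c + sd_c * (rho * z1 + sqrt(1 - rho^2) * z2)
    spectral_projection_pair(p, c_, c(1, 1))
  })
}

test_that("minimum-noise weight has its closed-form properties", {
  # perfectly anticorrelated equal-variance noise cancels at w = 0.5
  pr <- make_noise_pair(sd_p = 1, sd_c = 1, rho = -1)
  roi <- c(1, 64, 1, 64)
  expect_equal(compute_minimum_noise_weight(pr, roi, detrend = FALSE), 0.5,
               tolerance = 1e-10)

  # sd_p = 2 sd_c, uncorrelated: w = 1/5; cross-check with a brute-force
  # scan of the ROI variance over a weight grid
  pr2 <- make_noise_pair(sd_p = 2, sd_c = 1, rho = 0, seed = 2)
  w <- compute_minimum_noise_weight(pr2, roi, detrend = FALSE)
  grid <- seq(0, 1, by = 1e-4)
  v <- vapply(grid, function(g)
    var(as.vector(g * pr2$photoelectric_epl +
                    (1 - g) * pr2$compton_epl)), numeric(1))
  expect_equal(w, grid[which.min(v)], tolerance = 2e-4)
  expect_equal(w, 1 / 5, tolerance = 0.05)

  # minimizer property: returned weight beats the endpoints, any input
  for (s in 3:6) {
    prs <- make_noise_pair(sd_p = runif(1, 0.5, 2), sd_c = 1,
                           rho = runif(1, -0.95, 0.5), seed = s)
    ws <- compute_minimum_noise_weight(prs, roi, detrend = FALSE)
    vv <- function(g) var(as.vector(g * prs$photoelectric_epl +
                                      (1 - g) * prs$compton_epl))
    expect_lte(vv(ws), vv(0) + 1e-12)
    expect_lte(vv(ws), vv(1) + 1e-12)
  }

  const <- spectral_projection_pair(matrix(1, 16, 16), matrix(2, 16, 16),
                                    c(1, 1))
  expect_error(compute_minimum_noise_weight(const, c(1, 16, 1, 16)),
               "degenerate")
  expect_error(compute_minimum_noise_weight(pr, c(1, 4, 1, 4)), "64")
})

test_that("dictionary learning is deterministic and learns structure", {
  # constant image: nothing to train on
  expect_error(learn_dictionary(matrix(5, 32, 32), noise_sigma = 0.1),
               "featureless|constant")

  # noiseless stripes: some atom aligns with the stripe pattern
  img <- matrix(0, 48, 48)
  img[] <- rep(c(0, 0, 1, 1), length.out = 48)   # vertical stripes (rows)
  d <- learn_dictionary(img, patch_size = 8, n_atoms = 64,
                        noise_sigma = 0.05)
  stripe_patch <- matrix(rep(c(0, 0, 1, 1), 2), 8, 8)
  stripe_patch <- stripe_patch - mean(stripe_patch)
  stripe_patch <- stripe_patch / sqrt(sum(stripe_patch^2))
  cors <- abs(crossprod(d$atoms, as.vector(stripe_patch)))
  expect_gt(max(cors), 0.9)

  # bitwise determinism for a fixed seed
  withr::with_seed(3, noisy <- img + matrix(rnorm(48 * 48, 0, 0.1), 48, 48))
  d1 <- learn_dictionary(noisy, noise_sigma = 0.1, training_seed = 7)
  d2 <- learn_dictionary(noisy, noise_sigma = 0.1, training_seed = 7)
  expect_identical(d1$atoms, d2$atoms)
  expect_true(all(abs(colSums(d1$atoms^2) - 1) < 1e-12))
  expect_error(learn_dictionary(matrix(0, 48, 48), patch_size = 8,
                                n_atoms = 16, noise_sigma = 1), "n_atoms")
})

test_that("dictionary denoising reduces noise without destroying signal", {
  # a clean flat image passes through unchanged (patch means carry it)
  flat <- matrix(3, 32, 32)
  d <- dct_dict <- sdexa:::dct_dictionary(8, 64)
  dict <- structure(list(atoms = d, patch_size = 8, n_atoms = 64,
                         training_seed = 1L, sparsity_target = 8,
                         tolerance_gain = 1.1, noise_sigma = 0.1),
                    class = "patch_dictionary")
  expect_equal(denoise_image(flat, dict, 0.1), flat, tolerance = 1e-12)

  # synthetic edge + noise: RMSE against the clean image decreases
  clean <- matrix(0, 48, 48); clean[, 25:48] <- 2
  withr::with_seed(11, noisy <- clean + matrix(rnorm(48^2, 0, 0.25), 48, 48))
  dict2 <- learn_dictionary(noisy, noise_sigma = 0.25)
  den <- denoise_image(noisy, dict2, 0.25)
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
  # mean preserved to well within 0.1%
  expect_lt(abs(mean(den) - mean(noisy)) / abs(mean(noisy)), 1e-3)
  expect_error(denoise_image(noisy, dict2, -1), "positive")
})

test_that("local linear transform reproduces exact linear relations", {
  withr::with_seed(5, g <- matrix(rnorm(40 * 40), 40, 40))
  basis <- 2 * g + 1
  # globally linear relation, denoised reference equal to the raw one:
  # the transform must return the same linear map of it
  out <- local_linear_transform(basis, g, g, window_radius = 4,
                                regularizer = 1e-12)
  expect_equal(out, 2 * g + 1, tolerance = 1e-6)

  # pass-through: with a locally affine relation between reference and
  # basis, an identical (already clean) reference reproduces the raw basis
  rows <- row(g) / 10
  b2 <- (1 + 0.3 * sin(rows)) * g + rows
  out2 <- local_linear_transform(b2, g, g, window_radius = 4,
                                 regularizer = 1e-10)
  expect_lt(sqrt(mean((out2 - b2)^2)) / sd(b2), 0.1)
  expect_error(local_linear_transform(b2, g, g, window_radius = 30), "window")
})

test_that("denoise pipeline reduces anticorrelation and preserves the signal", {
  m <- fixture_model()
  vol <- fixture_flat_phantom()
  geo <- scout_geometry(n_columns = 192, z_collimation_rows = 2,
                        row_pitch = 1, table_step = 2)

  # noiseless input passes through unchanged
  sc0 <- simulate_scout(vol, geo, scout_acquisition(fluence_per_pixel = Inf),
                        m)
  dn0 <- denoise_pipeline(sc0, model = m)
  expect_false(dn0$report$denoised)
  expect_identical(dn0$denoised$photoelectric_epl, sc0$photoelectric_epl)

  # noisy input: SNR up, |anticorrelation| down, minimum-noise image
  # preserved at pixel level, ROI means stable
  sc <- simulate_scout(vol, geo, scout_acquisition(seed = 21), m)
  dn <- denoise_pipeline(sc, model = m)
  rep <- dn$report
  expect_true(rep$denoised)
  expect_gt(rep$after$photoelectric$snr, rep$before$photoelectric$snr)
  expect_lt(abs(rep$after$anticorrelation), abs(rep$before$anticorrelation))
  expect_lt(rep$mean_abmd_shift_pct, 2)

  w <- rep$weight
  mn_raw <- w * sc$photoelectric_epl + (1 - w) * sc$compton_epl
  mn_den <- w * dn$denoised$photoelectric_epl +
    (1 - w) * dn$denoised$compton_epl
  sig_ph <- estimate_noise_sigma(sc$photoelectric_epl, rep$noise_roi)
  expect_lt(max(abs(mn_den - mn_raw)), 0.5 * sig_ph)

  roi <- rep$noise_roi
  mean_before <- roi_metrics(sc$photoelectric_epl, roi = roi)$mean
  mean_after <- roi_metrics(dn$denoised$photoelectric_epl, roi = roi)$mean
  expect_lt(abs(mean_after - mean_before) / abs(mean_before), 0.02)
})

test_that("denoising a pure-noise flat field does not hallucinate", {
  withr::with_seed(31, {
    p <- matrix(rnorm(64 * 64, 10, 0.8), 64, 64)
    c_ <- matrix(rnorm(64 * 64, 10, 0.8), 64, 64)
  })
  pr <- spectral_projection_pair(p, c_, c(1, 1))
  dn <- denoise_pipeline(pr, noise_roi = c(1, 64, 1, 64))
  out <- dn$denoised$photoelectric_epl
  expect_lt(var(as.vector(out)), var(as.vector(p)))
  se <- sd(p) / 64
  expect_lt(abs(mean(out) - mean(p)), 3 * se)
})

test_that("minimum-noise weights map to interpretable virtual energies", {
  m <- fixture_model()
  cf <- m$basis_coefficients
  # round trip: the energy returned reproduces the weight of its mixture
  for (w in c(0.05, 0.1, 0.3)) {
    e <- weight_virtual_energy(w, m)
    p <- cf["photoelectric", "water"] * m$photoelectric_basis(e)
    c_ <- cf["compton", "water"] * m$compton_basis(e)
    expect_equal(p / (p + c_), w, tolerance = 1e-6)
  }
  # photoelectric share falls with energy, so higher weight = lower energy
  expect_gt(weight_virtual_energy(0.3, m), 30)
  expect_gt(weight_virtual_energy(0.3, m), weight_virtual_energy(0.4, m))
  expect_true(is.na(weight_virtual_energy(0.99, m)))
  expect_error(weight_virtual_energy(1.2, m), "0, 1")
})
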