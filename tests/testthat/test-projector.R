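test_that("empty volumes project to all-zero maps", {
  geo <- fixture_geometry(n_columns = 16)
  p <- forward_project(array(0, c(16, 16, 16)), geo, spacing = c(2, 2, 2))
  expect_true(all(p == 0))
  expect_equal(dim(p)[2], 16L)
})

test_that("uniform cylinder central column matches the analytic chord", {
  # cylinder along z: radius 20 mm, density 0.15 g/mL (150 mg/mL).
  # central ray chord = 2r -> areal density 2 * 2 cm * 0.15 = 0.6 g/cm^2
  dims <- c(96, 96, 8); sp <- c(1, 1, 4)
  x <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
  y <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp[2]
  vol <- array(0, dims)
  disc <- outer(x^2, y^2, `+`) <= 20^2
  for (k in seq_len(dims[3])) vol[, , k] <- disc * 0.15
  geo <- scout_geometry(n_columns = 65, z_collimation_rows = 1,
                        row_pitch = 4, table_step = 4)
  p <- forward_project(vol, geo, spacing = sp)
  central <- p[nrow(p) %/% 2, 33]   # odd column count: exact center column
  expect_equal(central, 0.6, tolerance = 0.005)
})

test_that("rotationally symmetric phantoms project equally in AP and lateral", {
  dims <- c(40, 40, 12); sp <- c(2, 2, 3)
  x <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
  vol <- array(0, dims)
  disc <- outer(x^2, x^2, `+`) <= 30^2
  for (k in seq_len(dims[3])) vol[, , k] <- disc * 1.0
  ap <- forward_project(vol, fixture_geometry(), spacing = sp)
  lat_geo <- fixture_geometry(); lat_geo$view_angle <- 90
  lat <- forward_project(vol, lat_geo, spacing = sp)
  expect_equal(as.vector(ap), as.vector(lat), tolerance = 1e-10)
})

test_that("projection is linear in the volume", {
  withr::with_seed(4, {
    a <- array(runif(16^3), c(16, 16, 16))
    b <- array(runif(16^3), c(16, 16, 16))
  })
  geo <- fixture_geometry(n_columns = 16)
  pa <- forward_project(a, geo, spacing = c(2, 2, 2))
  pb <- forward_project(b, geo, spacing = c(2, 2, 2))
  pab <- forward_project(2 * a + 3 * b, geo, spacing = c(2, 2, 2))
  expect_equal(unclass(pab), 2 * unclass(pa) + 3 * unclass(pb),
               tolerance = 1e-12)
})

test_that("plane-crossing integrator agrees with a dense-sampling oracle", {
  withr::with_seed(9, vol <- array(runif(8^3), c(8, 8, 8)))
  sp <- c(1.5, 1.5, 1.5)
  rays <- sdexa:::scout_rays(scout_geometry(fan_angle = 4, n_columns = 16,
                                            z_collimation_rows = 1,
                                            row_pitch = 1, table_step = 3),
                             c(-6, 6))
  li <- sdexa:::ray_integrals(list(vol), sp, rays$p0, rays$dir)
  hits <- which(li[, 1] > 0)
  expect_gt(length(hits), 4)
  withr::with_seed(2, pick <- sample(hits, min(8L, length(hits))))
  for (r in pick) {
    ref <- oracle_ray_integral(vol, sp, rays$p0[r, ], rays$dir[r, ])
    expect_lt(abs(li[r, 1] - ref) / max(ref, 1e-12), 1e-3)
  }
})

test_that("areal values are invariant to the detector distance", {
  vol <- fixture_small_phantom()
  g1 <- fixture_geometry()
  g2 <- fixture_geometry(); g2$source_to_detector <- 2 * g1$source_to_detector
  p1 <- forward_project(vol, g1)
  p2 <- forward_project(vol, g2)
  expect_equal(as.vector(p1), as.vector(p2), tolerance = 1e-12)
})

test_that("mask and density projections are mutually consistent", {
  # projecting density*mask and dividing by the mask path length recovers
  # the uniform trabecular density inside the 2D mask
  vol <- fixture_small_phantom()
  geo <- fixture_geometry()
  trab <- array(0, dim(vol$labels)); trab[vol$labels == 12L] <- 1
  dens <- forward_project(trab * 0.15, geo, spacing = vol$voxel_spacing)
  path <- forward_project(trab, geo, quantity = "binary",
                          spacing = vol$voxel_spacing)
  sel <- path > 0.5 * max(path)
  ratio <- dens[sel] / path[sel]
  expect_true(all(abs(ratio - 0.15) / 0.15 < 0.01))
})

test_that("projected masks follow coverage-fraction geometry", {
  vol <- fixture_small_phantom()
  geo <- fixture_geometry(n_columns = 128)
  # full-thickness slab: fraction 0.5 keeps the silhouette interior
  dims <- c(32, 32, 16)
  lab <- array(0L, dims); lab[9:24, , ] <- 12L
  m1 <- project_mask(lab, geo, coverage_fraction = 0.5, spacing = c(2, 2, 2))
  path <- forward_project(array(as.numeric(lab == 12L), dims), geo,
                          quantity = "binary", spacing = c(2, 2, 2))
  expect_true(all((m1 == 12L) == (path >= 0.5 * max(path) & path > 0)))

  # sphere: projected mask area shrinks monotonically with the fraction
  x <- (seq_len(32) - 16.5) * 2
  sph <- array(0L, dims[c(1, 1, 3)])
  for (k in seq_len(dims[3])) {
    z <- (k - (dims[3] + 1) / 2) * 2
    sph[, , k] <- ifelse(outer(x^2, x^2, `+`) + z^2 <= 24^2, 12L, 0L)
  }
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(f)
    sum(project_mask(sph, geo, coverage_fraction = f,
                     spacing = c(2, 2, 2)) == 12L), numeric(1))
  expect_true(all(diff(areas) < 0))

  # cylinder chord threshold: fraction f keeps |x| <= r*sqrt(1-f^2)
  r_mm <- 24
  cyl <- array(0L, c(48, 48, 8))
  xc <- (seq_len(48) - 24.5) * 2
  disc <- outer(xc^2, xc^2, `+`) <= r_mm^2
  for (k in 1:8) cyl[, , k] <- ifelse(disc, 12L, 0L)
  f <- 0.25
  mk <- project_mask(cyl, geo, coverage_fraction = f, spacing = c(2, 2, 2))
  cols <- which(apply(mk == 12L, 2, any))
  px <- attr(mk, "pixel_spacing")[["column"]]
  width_mm <- length(cols) * px
  expect_lt(abs(width_mm - 2 * r_mm * sqrt(1 - f^2)), 2.2 * px)

  expect_warning(project_mask(array(0L, c(16, 16, 16)), geo,
                              which_labels = 11L, spacing = c(2, 2, 2)),
                 "empty")
})
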