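#' Simulate virtual monoenergetic CT volumes
#'
#' Forward-composes the 50/200 keV (by default) attenuation volumes from the
#' phantom's water and hydroxyapatite densities:
#' `mu_E = (mu/rho)_water(E) * rho_water + (mu/rho)_bone(E) * rho_bone`,
#' with densities in g/mL and attenuation in 1/cm. Optional zero-mean
#' Gaussian noise of standard deviation `noise_sd` (1/cm) is added
#' independently per volume.
#'
#' @param volume a `labeled_volume` from [build_phantom()].
#' @param model an [attenuation_model()].
#' @param energies_kev the two energies, keV.
#' @param noise_sd Gaussian noise sd in 1/cm (default 0: noiseless ground
#'   truth).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return object of class `spectral_volume_pair` with `mu_low`, `mu_high`
#'   (3D arrays, 1/cm), the energies and the voxel spacing.
#' @export
simulate_monoenergetic <- function(volume, model, energies_kev = c(50, 200),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(inherits(volume, "labeled_volume"),
            inherits(model, "attenuation_model"))
  muw <- mass_attenuation(model, "water", energies_kev)
  mub <- mass_attenuation(model, "hydroxyapatite", energies_kev)
  rw <- volume$water_density
  rb <- volume$hydroxyapatite_density / 1000  # mg/mL -> g/mL
  mu_low <- muw[1] * rw + mub[1] * rb
  mu_high <- muw[2] * rw + mub[2] * rb
  if (noise_sd > 0) {
    local_seed(seed, {
      mu_low <- mu_low + array(rnorm(length(mu_low), 0, noise_sd),
                               dim(mu_low))
      mu_high <- mu_high + array(rnorm(length(mu_high), 0, noise_sd),
                                 dim(mu_high))
    })
  }
  structure(
    list(mu_low = mu_low, mu_high = mu_high, energies_kev = energies_kev,
         voxel_spacing = volume$voxel_spacing),
    class = "spectral_volume_pair"
  )
}

#' Scout acquisition settings
#'
#' Two effective monoenergetic detector channels with independent Poisson
#' counting statistics, emulating a dual-layer detector running a low-dose
#' scout. The default fluence is chosen so that the photoelectric
#' equivalent-path-length map has a soft-tissue signal-to-noise ratio of
#' about 5 through an abdomen-sized water path.
#'
#' @param channel_energies keV pair, low < high, both within (30, 120).
#' @param fluence_per_pixel expected photon count per channel in air; `Inf`
#'   disables noise.
#' @param seed RNG seed for the Poisson draw.
#' @export
scout_acquisition <- function(channel_energies = c(55, 75),
                              fluence_per_pixel = 2e4, seed = 1L) {
  e <- channel_energies
  if (length(e) != 2 || e[1] >= e[2] || any(e <= 30) || any(e >= 120)) {
    stop_sdexa("channel energies must satisfy 30 < low < high < 120 keV")
  }
  if (fluence_per_pixel <= 0) stop_sdexa("fluence must be positive")
  structure(list(channel_energies = e, fluence_per_pixel = fluence_per_pixel,
                 seed = as.integer(seed)),
            class = "scout_acquisition")
}

#' Construct a spectral projection pair
#'
#' Container for the two basis line-integral maps of a spectral scout,
#' expressed as water-equivalent path lengths (cm).
#'
#' @param photoelectric_epl,compton_epl matrices, water-equivalent cm.
#' @param pixel_spacing mm pair (z, column).
#' @param qc optional list of QC entries (e.g. clamped-pixel fraction).
#' @export
spectral_projection_pair <- function(photoelectric_epl, compton_epl,
                                     pixel_spacing, qc = list()) {
  stopifnot(identical(dim(photoelectric_epl), dim(compton_epl)),
            all(pixel_spacing > 0))
  structure(list(photoelectric_epl = photoelectric_epl,
                 compton_epl = compton_epl,
                 pixel_spacing = pixel_spacing, qc = qc),
            class = "spectral_projection_pair")
}

#' @export
print.spectral_projection_pair <- function(x, ...) {
  cat("<spectral_projection_pair>", paste(dim(x$photoelectric_epl),
                                          collapse = "x"),
      "pixels;", if (length(x$qc)) paste("clamped fraction",
                                         signif(x$qc$clamp_fraction %||% 0,
                                                3)) else "", "\n")
  invisible(x)
}

#' Simulate a two-channel spectral scout acquisition
#'
#' Ray-traces the phantom's water and hydroxyapatite densities into areal
#' densities per detector pixel, evaluates the channel line integrals at the
#' two effective energies, draws Poisson counts
#' `N ~ Poisson(fluence * exp(-L))`, forms measured line integrals
#' `-log(max(N, 1)/fluence)` (zero counts are clamped to 1 and recorded in
#' the QC block), and solves the per-pixel 2x2 channel system for the
#' photoelectric and Compton basis line integrals, returned as
#' water-equivalent path lengths in cm.
#'
#' @param volume a `labeled_volume`.
#' @param geometry a [scout_geometry()].
#' @param acq a [scout_acquisition()]; `fluence_per_pixel = Inf` gives the
#'   noiseless limit.
#' @param model an [attenuation_model()].
#' @return a [spectral_projection_pair()] whose `qc` records the clamp
#'   fraction, seed and fluence.
#' @export
simulate_scout <- function(volume, geometry, acq, model) {
  stopifnot(inherits(volume, "labeled_volume"),
            inherits(geometry, "scout_geometry"),
            inherits(acq, "scout_acquisition"),
            inherits(model, "attenuation_model"))
  ad <- project_volumes(list(volume$water_density,
                             volume$hydroxyapatite_density / 1000),
                        volume$voxel_spacing, geometry)
  W <- ad[[1]] / 10   # areal densities, g/cm^2
  B <- ad[[2]] / 10
  e <- acq$channel_energies
  muw <- mass_attenuation(model, "water", e)
  mub <- mass_attenuation(model, "hydroxyapatite", e)
  L1 <- muw[1] * W + mub[1] * B
  L2 <- muw[2] * W + mub[2] * B

  clamp_fraction <- 0
  if (is.finite(acq$fluence_per_pixel)) {
    N0 <- acq$fluence_per_pixel
    local_seed(acq$seed, {
      n1 <- rpois(length(L1), N0 * exp(-L1))
      n2 <- rpois(length(L2), N0 * exp(-L2))
    })
    clamp_fraction <- mean(c(n1, n2) == 0)
    L1 <- matrix(-log(pmax(n1, 1) / N0), nrow(L1))
    L2 <- matrix(-log(pmax(n2, 1) / N0), nrow(L2))
  }

  # channel system: L(E) = P * f_ph(E) + C * f_kn(E)
  M <- rbind(c(model$photoelectric_basis(e[1]), model$compton_basis(e[1])),
             c(model$photoelectric_basis(e[2]), model$compton_basis(e[2])))
  dM <- det(M)
  if (abs(dM) < 1e-12 || kappa(M) > 1e6) {
    stop_sdexa("channel matrix is not invertible for energies ",
               paste(e, collapse = "/"))
  }
  P <- (M[2, 2] * L1 - M[1, 2] * L2) / dM
  C <- (-M[2, 1] * L1 + M[1, 1] * L2) / dM
  cf <- model$basis_coefficients   # rows ph/compton, cols water/bone
  spectral_projection_pair(
    photoelectric_epl = P / cf["photoelectric", "water"],
    compton_epl = C / cf["compton", "water"],
    pixel_spacing = projection_pixel_spacing(geometry),
    qc = list(clamp_fraction = clamp_fraction, seed = acq$seed,
              fluence_per_pixel = acq$fluence_per_pixel,
              channel_energies = e)
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient trabecular volumetric BMD uniformly over `vbmd_range`
#' (shared by the four vertebrae of a patient), jitters the anatomy (body
#' size, vertebra position, cortical and spinous mineral density) within
#' physiological bounds, and simulates for each patient the labelled volume,
#' the noiseless monoenergetic volume pair and the noisy spectral scout.
#'
#' @param n number of patients (>= 2).
#' @param vbmd_range mg/mL pair within `[20, 300]`; a degenerate range
#'   (min = max) produces a constant cohort.
#' @param geometry a [scout_geometry()] (AP view for the scout).
#' @param acq a [scout_acquisition()]; per-patient seeds are derived from
#'   `seed`.
#' @param seed master RNG seed; the same seed reproduces the cohort exactly.
#' @param phantom_shape,voxel_spacing phantom grid (kept moderate by default
#'   so a cohort simulates in minutes).
#' @param jitter relative anatomical jitter amplitude (0 disables).
#' @return list of patients; each has elements `volume` (labeled_volume),
#'   `monoenergetic` (spectral_volume_pair), `scout`
#'   (spectral_projection_pair) and `truth` (one-row tibble with patient id,
#'   true trabecular vBMD and status from [classify_status()]).
#' @export
generate_cohort <- function(n, vbmd_range = c(40, 200),
                            geometry = scout_geometry(n_columns = 64,
                                                      z_collimation_rows = 2,
                                                      row_pitch = 2),
                            acq = scout_acquisition(), seed = 1L,
                            phantom_shape = c(64, 64, 40),
                            voxel_spacing = c(3, 3, 3),
                            jitter = 1) {
  if (n < 2) stop_sdexa("n must be >= 2")
  if (length(vbmd_range) != 2 || any(vbmd_range < 20) ||
        any(vbmd_range > 300) || vbmd_range[1] > vbmd_range[2]) {
    stop_sdexa("vbmd_range must be an increasing pair within [20, 300]")
  }
  model <- attenuation_model()
  draws <- local_seed(seed, {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      vbmd_true = runif(n, vbmd_range[1], vbmd_range[2]),
      body_a = 90 * (1 + jitter * runif(n, -0.05, 0.05)),
      body_b = 70 * (1 + jitter * runif(n, -0.05, 0.05)),
      off_x = jitter * runif(n, -3, 3),
      off_y = jitter * runif(n, -3, 3),
      cortical_ha = 350 + jitter * runif(n, 0, 150),
      spinous_ha = 100 + jitter * runif(n, 0, 100),
      spinous_len = 28 + jitter * runif(n, -3, 3),
      scout_seed = sample.int(2^30, n)
    )
  })
  purrr::pmap(draws, function(patient_id, vbmd_true, body_a, body_b, off_x,
                              off_y, cortical_ha, spinous_ha, spinous_len,
                              scout_seed) {
    spec <- phantom_spec(
      volume_shape = phantom_shape, voxel_spacing = voxel_spacing,
      body_ellipse = c(body_a, body_b),
      vertebrae = default_vertebrae(
        trabecular_hydroxyapatite = vbmd_true,
        cortical_hydroxyapatite = cortical_ha,
        spinous_hydroxyapatite = spinous_ha,
        spinous_process_length = spinous_len,
        center_y = 12 + off_y
      ) |> purrr::map(function(v) { v$center[1] <- off_x; v })
    )
    vol <- build_phantom(spec)
    mono <- simulate_monoenergetic(vol, model)
    acq_i <- acq; acq_i$seed <- as.integer(scout_seed)
    scout <- simulate_scout(vol, geometry, acq_i, model)
    truth <- tibble::tibble(patient_id = patient_id, vbmd_true = vbmd_true,
                            status = classify_status(vbmd_true))
    list(volume = vol, monoenergetic = mono, scout = scout, truth = truth)
  })
}
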