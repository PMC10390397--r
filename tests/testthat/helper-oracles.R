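# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately implemented with different algorithms than the package code
# they check.

# Dense-sampling ray tracer: integrates a voxel-constant volume by
# nearest-neighbour sampling at a very fine step. Converges to the exact
# piecewise-constant line integral as step -> 0; used as the independent
# check of the package's plane-crossing integrator.
oracle_ray_integral <- function(vol, spacing, p0, dir, step_frac = 1e-4) {
  dims <- dim(vol)
  # entry/exit of the voxel bounding box in world coordinates
  u0 <- p0 / spacing + (dims + 1) / 2
  du <- dir / spacing
  t0 <- 0; t1 <- Inf
  for (a in 1:3) {
    if (du[a] != 0) {
      ta <- (0.5 - u0[a]) / du[a]
      tb <- (dims[a] + 0.5 - u0[a]) / du[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    } else if (u0[a] < 0.5 || u0[a] > dims[a] + 0.5) return(0)
  }
  if (t1 <= t0) return(0)
  step <- min(spacing) * step_frac
  tt <- seq(t0 + step / 2, t1 - step / 2, by = step)
  iu <- pmin(pmax(floor(u0[1] + tt * du[1] + 0.5), 1), dims[1])
  iv <- pmin(pmax(floor(u0[2] + tt * du[2] + 0.5), 1), dims[2])
  iw <- pmin(pmax(floor(u0[3] + tt * du[3] + 0.5), 1), dims[3])
  sum(vol[cbind(iu, iv, iw)]) * step
}

# Pairwise-concordance AUC estimator with half credit for ties.
# Orientation: low scores indicate the positive class when positive_is_low.
oracle_auc_concordance <- function(scores, labels, positive_is_low = TRUE) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, n) {
    if (positive_is_low) (p < n) + 0.5 * (p == n) else (p > n) + 0.5 * (p == n)
  })
  mean(cmp)
}

# Normal-equations straight-line fit (independent of stats::lm).
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(x) - 2)
  covb <- s2 * solve(t(X) %*% X)
  list(intercept = beta[1], slope = beta[2],
       se_intercept = sqrt(covb[1, 1]), se_slope = sqrt(covb[2, 2]))
}

# Small shared fixtures (built once per test run)
fixture_env <- new.env()

fixture_model <- function() {
  if (is.null(fixture_env$model)) fixture_env$model <- attenuation_model()
  fixture_env$model
}

# a compact phantom: one vertebra, small grid -- fast to project
fixture_small_phantom <- function() {
  if (is.null(fixture_env$small_phantom)) {
    fixture_env$small_phantom <- build_phantom(phantom_spec(
      volume_shape = c(48, 48, 24), voxel_spacing = c(3, 3, 3),
      body_ellipse = c(65, 55),
      vertebrae = list(vertebra_spec("L2", center = c(0, 5, 0),
                                     spinous_process_length = 20))
    ))
  }
  fixture_env$small_phantom
}

# wide flat-bodied phantom: near-constant path length across the fan, used
# for homogeneous-ROI noise studies
fixture_flat_phantom <- function() {
  if (is.null(fixture_env$flat_phantom)) {
    fixture_env$flat_phantom <- build_phantom(phantom_spec(
      volume_shape = c(64, 64, 40), voxel_spacing = c(3, 3, 3),
      body_ellipse = c(400, 70),
      vertebrae = default_vertebrae()[2]
    ))
  }
  fixture_env$flat_phantom
}

fixture_geometry <- function(n_columns = 64) {
  scout_geometry(n_columns = n_columns, z_collimation_rows = 2,
                 row_pitch = 2)
}

# synthetic noiseless scout aBMD map shared by the registration tests
reg_fixture_map <- function() {
  if (is.null(fixture_env$reg_map)) {
    m <- fixture_model()
    vol <- build_phantom(phantom_spec())
    geo <- scout_geometry(n_columns = 128, z_collimation_rows = 2,
                          row_pitch = 1, table_step = 2)
    sc <- simulate_scout(vol, geo,
                         scout_acquisition(fluence_per_pixel = Inf), m)
    fixture_env$reg_map <- unclass(epl_to_abmd(sc, m))
  }
  fixture_env$reg_map
}
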