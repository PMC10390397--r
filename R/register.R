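#' 2D affine transform
#'
#' Resampling convention: the transform maps fixed-image pixel coordinates
#' (row, col) to moving-image coordinates about `fixed_center`, i.e.
#' `moving_coord = linear %*% (x - center) + center + translation`.
#'
#' @param linear 2x2 matrix; must be invertible with determinant in
#'   (0.5, 2.0).
#' @param translation length-2 pixel offset.
#' @param fixed_center length-2 pixel coordinate the linear part pivots on.
#' @export
affine_transform_2d <- function(linear = diag(2), translation = c(0, 0),
                                fixed_center = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  d <- det(linear)
  if (!(d > 0.5 && d < 2.0)) {
    stop_sdexa("transform determinant ", signif(d, 4),
               " outside the accepted (0.5, 2.0) range")
  }
  structure(list(linear = linear, translation = as.numeric(translation),
                 fixed_center = as.numeric(fixed_center)),
            class = "affine_transform_2d")
}

#' @export
print.affine_transform_2d <- function(x, ...) {
  cat("<affine_transform_2d> translation",
      paste(signif(x$translation, 4), collapse = ", "),
      "px; linear:\n")
  print(signif(x$linear, 5))
  invisible(x)
}

transform_coords <- function(transform, ri, ci) {
  d <- cbind(ri - transform$fixed_center[1], ci - transform$fixed_center[2])
  m <- d %*% t(transform$linear)
  list(ri = m[, 1] + transform$fixed_center[1] + transform$translation[1],
       ci = m[, 2] + transform$fixed_center[2] + transform$translation[2])
}

warp_image <- function(moving, transform, dim_fixed = dim(moving),
                       interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  gr <- expand.grid(ri = seq_len(dim_fixed[1]), ci = seq_len(dim_fixed[2]))
  tc <- transform_coords(transform, gr$ri, gr$ci)
  v <- if (interp == "linear") bilinear_sample(moving, tc$ri, tc$ci)
  else nearest_sample(moving, tc$ri, tc$ci)
  matrix(v, dim_fixed[1], dim_fixed[2])
}

downsample2 <- function(img) {
  nr <- nrow(img) %/% 2L; nc <- ncol(img) %/% 2L
  if (nr < 1 || nc < 1) return(img)
  i <- seq_len(2L * nr); j <- seq_len(2L * nc)
  x <- img[i, j, drop = FALSE]
  0.25 * (x[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
            x[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
            x[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE] +
            x[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE])
}

msd_metric <- function(moving, fixed, transform) {
  w <- warp_image(moving, transform, dim(fixed))
  mean((w - fixed)^2)
}

#' Register a moving aBMD map to a fixed aBMD map
#'
#' Two-stage intensity-based registration minimizing the mean squared
#' difference: a translation-only stage followed by a full affine stage,
#' both run over a coarse-to-fine image pyramid with Nelder-Mead
#' optimization at each level. Deterministic. Solutions with an affine
#' determinant outside (0.5, 2.0), or whose final metric exceeds the
#' initial one, are rejected.
#'
#' @param moving,fixed matrices (e.g. [abmd_map()]s) in the same units.
#' @param levels number of pyramid levels (coarsest has each dimension
#'   divided by `2^(levels-1)`).
#' @param max_iterations optimizer iteration cap per level.
#' @return list with `transform` (an [affine_transform_2d()]), `warped`
#'   (moving resampled into the fixed frame), and `metric` (final MSD).
#' @export
register_2d <- function(moving, fixed, levels = 3, max_iterations = 200) {
  moving <- unclass(as.matrix(moving)); fixed <- unclass(as.matrix(fixed))
  if (!all(is.finite(moving)) || !all(is.finite(fixed))) {
    stop_sdexa("maps must be finite for registration")
  }
  pyr_m <- list(moving); pyr_f <- list(fixed)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr_m[[l]])) < 12 || min(dim(pyr_f[[l]])) < 12) break
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]])
  }
  nlev <- length(pyr_m)
  center <- (dim(fixed) + 1) / 2

  # parameters: translation (t1, t2) then affine deviation (4 entries)
  trans <- c(0, 0)
  lin <- diag(2)
  for (l in rev(seq_len(nlev))) {
    sc <- 2^(l - 1)
    mv <- pyr_m[[l]]; fx <- pyr_f[[l]]
    ctr <- (dim(fx) + 1) / 2
    make_tf <- function(par, linear) {
      structure(list(linear = linear,
                     translation = par, fixed_center = ctr),
                class = "affine_transform_2d")
    }
    # translation stage; at the coarsest level an exhaustive integer-shift
    # scan seeds the optimizer, so periodic anatomy (evenly spaced
    # vertebrae) cannot trap it in a half-period local minimum
    obj_t <- function(par) msd_metric(mv, fx, make_tf(par, lin))
    t_start <- trans / sc
    if (l == nlev) {
      span <- pmax(2L, floor(dim(fx) / 4))
      grid <- expand.grid(r = -span[1]:span[1], c = -span[2]:span[2])
      vals <- vapply(seq_len(nrow(grid)), function(k)
        obj_t(c(grid$r[k], grid$c[k])), numeric(1))
      t_start <- unlist(grid[which.min(vals), ], use.names = FALSE)
    }
    ot <- optim(t_start, obj_t, method = "Nelder-Mead",
                control = list(maxit = max_iterations, reltol = 1e-10))
    trans <- ot$par * sc
    # affine stage (skip at the coarsest level: too few pixels); the
    # refinement is kept only if it improves on the translation solution,
    # which guards against aliased minima of the periodic vertebra pattern
    if (l < nlev || nlev == 1) {
      obj_a <- function(par) {
        L <- matrix(par[1:4], 2, 2)
        if (!(det(L) > 0.5 && det(L) < 2)) return(1e12)
        msd_metric(mv, fx, make_tf(par[5:6], L))
      }
      start <- c(as.vector(lin), trans / sc)
      oa <- optim(start, obj_a, method = "Nelder-Mead",
                  control = list(maxit = 4 * max_iterations,
                                 reltol = 1e-12))
      if (oa$value <= obj_a(start)) {
        lin <- matrix(oa$par[1:4], 2, 2)
        trans <- oa$par[5:6] * sc
      }
    }
  }

  tf <- affine_transform_2d(lin, trans, center)
  final <- msd_metric(moving, fixed, tf)
  initial <- msd_metric(moving, fixed,
                        affine_transform_2d(diag(2), c(0, 0), center))
  if (final > initial + 1e-12) {
    stop_sdexa("registration diverged: final metric ", signif(final, 4),
               " exceeds initial ", signif(initial, 4))
  }
  list(transform = tf, warped = warp_image(moving, tf, dim(fixed)),
       metric = final)
}

#' Resample a labelled 2D mask through a transform
#'
#' Nearest-neighbour resampling preserving label identities; pixels mapping
#' outside the moving mask become background (0).
#'
#' @param mask2d integer matrix of labels.
#' @param transform an [affine_transform_2d()].
#' @param dim_out output dimensions; defaults to the mask's.
#' @return integer matrix of labels.
#' @export
apply_transform <- function(mask2d, transform, dim_out = dim(mask2d)) {
  stopifnot(inherits(transform, "affine_transform_2d"))
  out <- warp_image(unclass(as.matrix(mask2d)), transform, dim_out,
                    interp = "nearest")
  matrix(as.integer(out), dim_out[1], dim_out[2])
}

#' Invert an affine transform
#' @param transform an [affine_transform_2d()].
#' @export
invert_transform <- function(transform) {
  Li <- solve(transform$linear)
  affine_transform_2d(Li, -Li %*% transform$translation,
                      transform$fixed_center)
}
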