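#' Specify a digital lumbar-spine phantom
#'
#' The phantom is an abdomen-like soft-tissue ellipse (extruded along the
#' table axis z) containing up to four simplified vertebrae. Each vertebra is
#' a vertical cylinder with a trabecular core, a cortical shell, and a
#' posterior spinous-process block (so that anterior-posterior projections
#' overlap the spinous process with the vertebral body while lateral
#' projections separate them).
#'
#' World coordinates are in mm with the origin at the volume centre;
#' x = patient left-right, y = anterior(-)/posterior(+), z = table axis.
#'
#' @param volume_shape integer triple of voxel counts (x, y, z), all >= 16.
#' @param voxel_spacing mm triple, all positive.
#' @param body_ellipse semi-axes (x, y) in mm of the soft-tissue body.
#' @param soft_tissue_density water-equivalent density of soft tissue, g/mL,
#'   in (0.8, 1.2).
#' @param vertebrae list of [vertebra_spec()] entries (0 to 4).
#' @param seed integer; reserved for optional texture, geometry itself is
#'   deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64, 64, 40),
                         voxel_spacing = c(3, 3, 3),
                         body_ellipse = c(90, 70),
                         soft_tissue_density = 1.0,
                         vertebrae = default_vertebrae(),
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 16)) {
    stop_sdexa("volume_shape must be three integers, all >= 16")
  }
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0)) {
    stop_sdexa("voxel_spacing must be three positive numbers (mm)")
  }
  if (length(body_ellipse) != 2 || any(body_ellipse <= 0)) {
    stop_sdexa("body_ellipse must be two positive semi-axes (mm)")
  }
  if (soft_tissue_density <= 0.8 || soft_tissue_density >= 1.2) {
    stop_sdexa("soft_tissue_density must lie in (0.8, 1.2) g/mL")
  }
  if (length(vertebrae) > 4) stop_sdexa("at most 4 vertebrae are supported")
  for (v in vertebrae) stopifnot(inherits(v, "vertebra_spec"))
  labs <- vapply(vertebrae, function(v) v$label, character(1))
  if (anyDuplicated(labs)) stop_sdexa("duplicate vertebra labels")
  spec <- structure(
    list(volume_shape = volume_shape, voxel_spacing = voxel_spacing,
         body_ellipse = body_ellipse,
         soft_tissue_density = soft_tissue_density,
         vertebrae = vertebrae, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  check_vertebra_layout(spec)
  spec
}

#' Specify one vertebra of the phantom
#'
#' @param label one of "L1".."L4".
#' @param center mm triple (world coordinates, see [phantom_spec()]).
#' @param body_radius cylinder radius of the vertebral body, mm.
#' @param body_height cylinder height along z, mm.
#' @param cortical_thickness shell thickness, mm; must be < body_radius.
#' @param trabecular_hydroxyapatite trabecular mineral density, mg/mL, in
#'   `[0, 400]`.
#' @param cortical_hydroxyapatite cortical mineral density, mg/mL, must be
#'   >= the trabecular value.
#' @param spinous_process_length posterior extent of the spinous block, mm
#'   (0 disables the process).
#' @param spinous_hydroxyapatite mineral density of the spinous block, mg/mL.
#' @param spinous_width width (x) of the spinous block, mm.
#' @param spinous_height height (z) of the spinous block, mm.
#' @return object of class `vertebra_spec`.
#' @export
vertebra_spec <- function(label, center, body_radius = 17, body_height = 24,
                          cortical_thickness = 1.5,
                          trabecular_hydroxyapatite = 150,
                          cortical_hydroxyapatite = 450,
                          spinous_process_length = 28,
                          spinous_hydroxyapatite = 150,
                          spinous_width = 10, spinous_height = 14) {
  if (!label %in% c("L1", "L2", "L3", "L4")) {
    stop_sdexa("label must be one of L1..L4")
  }
  if (trabecular_hydroxyapatite < 0 || trabecular_hydroxyapatite > 400) {
    stop_sdexa("trabecular_hydroxyapatite must lie in [0, 400] mg/mL")
  }
  if (cortical_hydroxyapatite < trabecular_hydroxyapatite) {
    stop_sdexa("cortical_hydroxyapatite must be >= trabecular value")
  }
  if (!(body_radius > cortical_thickness && cortical_thickness > 0)) {
    stop_sdexa("need body_radius > cortical_thickness > 0")
  }
  structure(
    list(label = label, center = as.numeric(center),
         body_radius = body_radius, body_height = body_height,
         cortical_thickness = cortical_thickness,
         trabecular_hydroxyapatite = trabecular_hydroxyapatite,
         cortical_hydroxyapatite = cortical_hydroxyapatite,
         spinous_process_length = spinous_process_length,
         spinous_hydroxyapatite = spinous_hydroxyapatite,
         spinous_width = spinous_width, spinous_height = spinous_height),
    class = "vertebra_spec"
  )
}

#' Default L1-L4 stack used by the simulator
#'
#' @param trabecular_hydroxyapatite mg/mL, recycled over the four vertebrae.
#' @param center_y posterior offset of the vertebral bodies, mm.
#' @param ... passed to [vertebra_spec()].
#' @export
default_vertebrae <- function(trabecular_hydroxyapatite = 150,
                              center_y = 20, ...) {
  z <- c(L1 = 42, L2 = 14, L3 = -14, L4 = -42)
  tb <- rep_len(trabecular_hydroxyapatite, 4)
  purrr::map2(names(z), seq_along(z), function(lab, i) {
    vertebra_spec(lab, center = c(0, center_y, z[[i]]),
                  trabecular_hydroxyapatite = tb[i], ...)
  })
}

# label codes: 0 background, 1 soft tissue, 10+k trabecular, 20+k cortical,
# 30+k spinous, where k = 1..4 indexes L1..L4
label_code <- function(kind, vertebra) {
  k <- match(vertebra, c("L1", "L2", "L3", "L4"))
  switch(kind, trabecular = 10L + k, cortical = 20L + k, spinous = 30L + k)
}

label_dictionary <- function() {
  d <- c(background = 0L, soft_tissue = 1L)
  for (k in 1:4) {
    v <- c("L1", "L2", "L3", "L4")[k]
    d[paste0("trabecular_", v)] <- 10L + k
    d[paste0("cortical_", v)] <- 20L + k
    d[paste0("spinous_", v)] <- 30L + k
  }
  d
}

vertebra_bbox <- function(v) {
  # axis-aligned world bounding box including the spinous block
  r <- v$body_radius
  lo <- c(v$center[1] - max(r, v$spinous_width / 2),
          v$center[2] - r,
          v$center[3] - v$body_height / 2)
  hi <- c(v$center[1] + max(r, v$spinous_width / 2),
          v$center[2] + r + v$spinous_process_length,
          v$center[3] + v$body_height / 2)
  rbind(lo, hi)
}

check_vertebra_layout <- function(spec) {
  vs <- spec$vertebrae
  n <- length(vs)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- vertebra_bbox(vs[[i]]); b <- vertebra_bbox(vs[[j]])
      if (all(a[1, ] < b[2, ]) && all(b[1, ] < a[2, ])) {
        stop_sdexa("vertebrae ", vs[[i]]$label, " and ", vs[[j]]$label,
                   " overlap")
      }
    }
  }
  for (v in vs) {
    # the vertebra (incl. spinous tip) must lie within the body ellipse
    pts <- rbind(
      v$center[1:2] + c(v$body_radius, 0),
      v$center[1:2] - c(v$body_radius, 0),
      v$center[1:2] + c(0, v$body_radius + v$spinous_process_length),
      v$center[1:2] - c(0, v$body_radius)
    )
    e <- (pts[, 1] / spec$body_ellipse[1])^2 +
      (pts[, 2] / spec$body_ellipse[2])^2
    if (any(e > 1)) {
      stop_sdexa("vertebra ", v$label, " extends outside the body ellipse")
    }
  }
  invisible(spec)
}

# world coordinates (mm) of voxel centres along one axis
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Voxelize a phantom specification
#'
#' Renders the body ellipse and each vertebra into per-voxel water density,
#' hydroxyapatite density and label grids. The geometry is deterministic:
#' every voxel is classified by its centre coordinate. Bone voxels keep the
#' soft-tissue water density (mineral is added on top of the water
#' background), so the hydroxyapatite grid is exactly zero outside bone.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `labeled_volume` with elements `water_density`
#'   (g/mL), `hydroxyapatite_density` (mg/mL), `labels` (integer codes, see
#'   `attr(,"label_dictionary")`), and `voxel_spacing` (mm).
#' @examples
#' vol <- build_phantom(phantom_spec(vertebrae = list()))
#' max(vol$hydroxyapatite_density) # 0: no bone
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_vertebra_layout(spec)
  dims <- spec$volume_shape
  sp <- spec$voxel_spacing
  x <- axis_coords(dims[1], sp[1])
  y <- axis_coords(dims[2], sp[2])
  z <- axis_coords(dims[3], sp[3])

  labels <- array(0L, dims)
  water <- array(0, dims)
  ha <- array(0, dims)

  inside_xy <- outer(x^2 / spec$body_ellipse[1]^2,
                     y^2 / spec$body_ellipse[2]^2, `+`) <= 1
  body <- array(inside_xy, dims)   # recycled over z
  labels[body] <- 1L
  water[body] <- spec$soft_tissue_density

  for (v in spec$vertebrae) {
    dz <- abs(z - v$center[3])
    zin_body <- dz <= v$body_height / 2
    zin_spin <- dz <= v$spinous_height / 2
    r2 <- outer((x - v$center[1])^2, (y - v$center[2])^2, `+`)
    core <- r2 <= (v$body_radius - v$cortical_thickness)^2
    shell <- r2 <= v$body_radius^2 & !core
    spin_xy <- outer(abs(x - v$center[1]) <= v$spinous_width / 2,
                     y > v$center[2] + v$body_radius &
                       y <= v$center[2] + v$body_radius +
                         v$spinous_process_length, `&`)
    for (k in which(zin_body)) {
      lab <- labels[, , k]
      lab[shell] <- label_code("cortical", v$label)
      lab[core] <- label_code("trabecular", v$label)
      labels[, , k] <- lab
      h <- ha[, , k]
      h[shell] <- v$cortical_hydroxyapatite
      h[core] <- v$trabecular_hydroxyapatite
      ha[, , k] <- h
    }
    if (v$spinous_process_length > 0) {
      for (k in which(zin_spin)) {
        lab <- labels[, , k]
        lab[spin_xy] <- label_code("spinous", v$label)
        labels[, , k] <- lab
        h <- ha[, , k]
        h[spin_xy] <- v$spinous_hydroxyapatite
        ha[, , k] <- h
      }
    }
  }

  structure(
    list(water_density = water, hydroxyapatite_density = ha,
         labels = labels, voxel_spacing = sp),
    label_dictionary = label_dictionary(),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("<labeled_volume>", paste(d, collapse = "x"), "voxels at",
      paste(x$voxel_spacing, collapse = "x"), "mm\n")
  tb <- table(x$labels)
  dict <- attr(x, "label_dictionary")
  names(tb) <- names(dict)[match(names(tb), dict)]
  print(tb)
  invisible(x)
}
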