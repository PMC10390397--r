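#' Fan-beam scout acquisition geometry
#'
#' Describes the scout (topogram) geometry: a fan of rays in the axial plane
#' covering `n_columns` detector columns over `fan_angle` degrees, with the
#' source rotating about the table axis z by `view_angle` (0 = AP, 90 =
#' lateral). The z direction is scanned: the patient table steps by
#' `table_step` mm per projection row while a beam collimated to
#' `z_collimation_rows` detector rows (each `row_pitch` mm wide, referred to
#' the isocenter) is averaged per detector cell. Referring the row pitch to
#' the isocenter makes path integrals independent of the detector distance.
#'
#' @param fan_angle full fan angle, degrees, in (0, 180).
#' @param n_columns number of detector columns (>= 16).
#' @param source_to_isocenter mm.
#' @param source_to_detector mm; must exceed `source_to_isocenter`.
#' @param z_collimation_rows rows averaged per cell (>= 1).
#' @param row_pitch collimated row width at the isocenter, mm.
#' @param view_angle degrees about z; 0 = anterior-posterior, 90 = lateral.
#' @param table_step table translation per projection row, mm; defaults to
#'   the collimated beam width so slices abut.
#' @return object of class `scout_geometry`.
#' @export
scout_geometry <- function(fan_angle = 52.5, n_columns = 512,
                           source_to_isocenter = 570,
                           source_to_detector = 1040,
                           z_collimation_rows = 4, row_pitch = 1.0,
                           view_angle = 0,
                           table_step = z_collimation_rows * row_pitch) {
  if (!(fan_angle > 0 && fan_angle < 180)) {
    stop_sdexa("fan_angle must lie in (0, 180) degrees")
  }
  if (n_columns < 16) stop_sdexa("n_columns must be >= 16")
  if (!(source_to_isocenter > 0 && source_to_detector > source_to_isocenter)) {
    stop_sdexa("need 0 < source_to_isocenter < source_to_detector")
  }
  if (z_collimation_rows < 1) stop_sdexa("z_collimation_rows must be >= 1")
  if (row_pitch <= 0 || table_step <= 0) {
    stop_sdexa("row_pitch and table_step must be positive")
  }
  structure(
    list(fan_angle = fan_angle, n_columns = as.integer(n_columns),
         source_to_isocenter = source_to_isocenter,
         source_to_detector = source_to_detector,
         z_collimation_rows = as.integer(z_collimation_rows),
         row_pitch = row_pitch, view_angle = view_angle,
         table_step = table_step),
    class = "scout_geometry"
  )
}

#' @export
print.scout_geometry <- function(x, ...) {
  cat("<scout_geometry> fan", x$fan_angle, "deg /", x$n_columns,
      "columns, view", x$view_angle, "deg, SID", x$source_to_isocenter,
      "mm, z-collimation", x$z_collimation_rows, "x", x$row_pitch, "mm\n")
  invisible(x)
}

# Build source positions and unit directions for every ray of a scout
# acquisition over a volume of world z extent [z0, z1]. Returns a list with
# per-ray matrices and the (n_z, n_columns, n_rows) layout.
scout_rays <- function(geometry, z_extent) {
  g <- geometry
  th <- g$view_angle * pi / 180
  # source in the axial plane; view 0 puts the source anterior (y < 0),
  # rays travelling towards +y
  s_xy <- c(g$source_to_isocenter * sin(th), -g$source_to_isocenter * cos(th))
  d0 <- -s_xy / sqrt(sum(s_xy^2))
  n_z <- max(1L, floor((z_extent[2] - z_extent[1]) / g$table_step))
  z_tab <- z_extent[1] + (seq_len(n_z) - 0.5) *
    (z_extent[2] - z_extent[1]) / n_z
  gam <- ((seq_len(g$n_columns) - 0.5) / g$n_columns - 0.5) *
    g$fan_angle * pi / 180
  rows <- (seq_len(g$z_collimation_rows) - (g$z_collimation_rows + 1) / 2) *
    g$row_pitch
  # directions in the axial plane per column
  dx <- cos(gam) * d0[1] - sin(gam) * d0[2]
  dy <- sin(gam) * d0[1] + cos(gam) * d0[2]
  # z slope per collimated row (referred to the isocenter)
  sl <- rows / g$source_to_isocenter

  nray <- n_z * g$n_columns * g$z_collimation_rows
  # ordering: column fastest, then z position, then collimated row
  col_i <- rep(rep(seq_len(g$n_columns), n_z), g$z_collimation_rows)
  z_i <- rep(rep(seq_len(n_z), each = g$n_columns), g$z_collimation_rows)
  row_i <- rep(seq_len(g$z_collimation_rows), each = n_z * g$n_columns)

  dir <- cbind(dx[col_i], dy[col_i], sl[row_i])
  dir <- dir / sqrt(rowSums(dir^2))
  p0 <- cbind(rep(s_xy[1], nray), rep(s_xy[2], nray), z_tab[z_i])
  list(p0 = p0, dir = dir, n_z = n_z, n_columns = g$n_columns,
       n_rows = g$z_collimation_rows, z_table = z_tab, gamma = gam,
       col_i = col_i, z_i = z_i, row_i = row_i)
}

#' Exact-intersection line integrals through voxel volumes
#'
#' Traces rays through one or more volumes sharing a grid, accumulating the
#' exact intersection length of each ray with each voxel (Siddon-style plane
#' crossings), so piecewise-constant volumes are integrated exactly.
#'
#' @param volumes list of 3D arrays sharing dimensions.
#' @param spacing voxel spacing, mm triple.
#' @param p0 n x 3 matrix of ray origins (world mm, volume centred at 0).
#' @param dir n x 3 matrix of unit ray directions.
#' @return n x length(volumes) matrix of line integrals in (volume unit) * mm.
#' @keywords internal
ray_integrals <- function(volumes, spacing, p0, dir) {
  dims <- dim(volumes[[1]])
  for (v in volumes) stopifnot(identical(dim(v), dims))
  vols <- lapply(volumes, as.vector)
  nv <- length(vols)
  n <- nrow(p0)
  out <- matrix(0, n, nv)
  org <- -(dims + 1) / 2 * spacing   # world coord of voxel index 0 centre...
  # voxel centre i (1-based) sits at (i - (dims+1)/2) * spacing, so the
  # continuous voxel coordinate is u = x/spacing + (dims+1)/2 with voxel i
  # spanning [i-0.5, i+0.5]
  nxy <- dims[1] * dims[2]
  for (r in seq_len(n)) {
    u0 <- p0[r, ] / spacing + (dims + 1) / 2
    du <- dir[r, ] / spacing
    t0 <- 0; t1 <- Inf; ok <- TRUE
    for (a in 1:3) {
      if (du[a] != 0) {
        ta <- (0.5 - u0[a]) / du[a]
        tb <- (dims[a] + 0.5 - u0[a]) / du[a]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      } else if (u0[a] < 0.5 || u0[a] > dims[a] + 0.5) {
        ok <- FALSE; break
      }
    }
    if (!ok || t1 <= t0) next
    ts <- c(t0, t1)
    for (a in 1:3) {
      if (du[a] != 0) {
        ua <- u0[a] + t0 * du[a]; ub <- u0[a] + t1 * du[a]
        k0 <- ceiling(min(ua, ub) - 0.5); k1 <- floor(max(ua, ub) - 0.5)
        if (k1 >= k0) {
          ts <- c(ts, ((k0:k1) + 0.5 - u0[a]) / du[a])
        }
      }
    }
    ts <- sort(ts)
    ts <- ts[ts >= t0 - 1e-12 & ts <= t1 + 1e-12]
    len <- diff(ts)
    keep <- len > 1e-12
    if (!any(keep)) next
    tm <- (ts[-length(ts)] + ts[-1])[keep] / 2
    len <- len[keep]
    iu <- floor(u0[1] + tm * du[1] + 0.5)
    iv <- floor(u0[2] + tm * du[2] + 0.5)
    iw <- floor(u0[3] + tm * du[3] + 0.5)
    good <- iu >= 1 & iu <= dims[1] & iv >= 1 & iv <= dims[2] &
      iw >= 1 & iw <= dims[3]
    if (!all(good)) { iu <- iu[good]; iv <- iv[good]; iw <- iw[good]
                      len <- len[good] }
    if (!length(len)) next
    lin <- iu + (iv - 1) * dims[1] + (iw - 1) * nxy
    for (v in seq_len(nv)) out[r, v] <- sum(vols[[v]][lin] * len)
  }
  out
}

# Trace a scout geometry over shared volumes; returns list of projection
# matrices (n_z x n_columns), averaging the collimated rows per cell.
# Integrals are in (volume unit) * mm.
project_volumes <- function(volumes, spacing, geometry) {
  dims <- dim(volumes[[1]])
  zr <- c(-1, 1) * dims[3] * spacing[3] / 2
  rays <- scout_rays(geometry, zr)
  li <- ray_integrals(volumes, spacing, rays$p0, rays$dir)
  lapply(seq_along(volumes), function(v) {
    acc <- matrix(0, rays$n_z, rays$n_columns)
    # average over collimated rows
    m <- matrix(li[, v], ncol = rays$n_rows)
    vals <- rowMeans(m)
    acc[cbind(rays$z_i[seq_len(rays$n_z * rays$n_columns)],
              rays$col_i[seq_len(rays$n_z * rays$n_columns)])] <- vals
    acc
  })
}

projection_pixel_spacing <- function(geometry) {
  c(z = geometry$table_step,
    column = geometry$source_to_isocenter *
      (geometry$fan_angle * pi / 180) / geometry$n_columns)
}

#' Forward-project a volume into scout geometry
#'
#' Integrates a density or binary volume along every fan-beam scout ray.
#' Density volumes (g/mL) yield areal density maps in g/cm^2; binary volumes
#' yield intersection path length in cm. Collimated rows are averaged per
#' detector cell. The projection is linear in the input volume.
#'
#' @param volume 3D array; density in g/mL when `quantity = "density"`, or
#'   0/1 when `quantity = "binary"`; alternatively a `labeled_volume`, whose
#'   hydroxyapatite grid (converted from mg/mL) is projected.
#' @param geometry a [scout_geometry()].
#' @param quantity `"density"` or `"binary"`.
#' @param spacing voxel spacing, mm triple (taken from a `labeled_volume`
#'   automatically).
#' @return object of class `projected_map`: a matrix (rows = table
#'   z-positions, columns = detector columns) with the geometry and pixel
#'   spacing attached.
#' @export
forward_project <- function(volume, geometry, quantity = c("density",
                                                           "binary"),
                            spacing = NULL) {
  quantity <- match.arg(quantity)
  if (inherits(volume, "labeled_volume")) {
    spacing <- volume$voxel_spacing
    volume <- volume$hydroxyapatite_density / 1000
  }
  if (is.null(spacing)) stop_sdexa("voxel spacing is required")
  stopifnot(inherits(geometry, "scout_geometry"), length(dim(volume)) == 3)
  vals <- project_volumes(list(volume), spacing, geometry)[[1]]
  vals <- vals / 10   # unit*mm -> unit*cm: g/mL*cm = g/cm^2, or cm for binary
  if (any(volume != 0) && all(vals == 0)) {
    warning("volume lies entirely outside the fan; projection is all zero")
  }
  structure(vals,
            pixel_spacing = projection_pixel_spacing(geometry),
            geometry = geometry, quantity = quantity,
            class = c("projected_map", "matrix", "array"))
}

#' Project a 3D label mask into labelled 2D masks
#'
#' Each vertebra label is projected as a binary volume; its path-length map
#' is thresholded at `coverage_fraction` of that label's maximum projected
#' path. Pixels covered by several labels are assigned to the label with the
#' larger path length.
#'
#' @param labels 3D integer array of label codes, or a `labeled_volume`.
#' @param geometry a [scout_geometry()].
#' @param which_labels integer codes to project; defaults to the trabecular
#'   codes present.
#' @param coverage_fraction threshold fraction in (0, 1].
#' @param spacing mm triple if `labels` is a bare array.
#' @return integer matrix (n_z x n_columns) of label codes, 0 = background,
#'   with the per-label maximum path lengths attached as an attribute.
#' @export
project_mask <- function(labels, geometry, which_labels = NULL,
                         coverage_fraction = 0.25, spacing = NULL) {
  if (inherits(labels, "labeled_volume")) {
    spacing <- labels$voxel_spacing
    labels <- labels$labels
  }
  if (is.null(spacing)) stop_sdexa("voxel spacing is required")
  if (!(coverage_fraction > 0 && coverage_fraction <= 1)) {
    stop_sdexa("coverage_fraction must lie in (0, 1]")
  }
  if (is.null(which_labels)) {
    present <- sort(unique(as.vector(labels)))
    which_labels <- present[present >= 11 & present <= 14]
  }
  bins <- lapply(which_labels, function(lb) {
    b <- array(0, dim(labels)); b[labels == lb] <- 1; b
  })
  empty <- vapply(bins, function(b) all(b == 0), logical(1))
  if (any(empty)) {
    warning("empty label(s): ", paste(which_labels[empty], collapse = ", "))
  }
  maps <- project_volumes(bins, spacing, geometry)
  out <- matrix(0L, nrow(maps[[1]]), ncol(maps[[1]]))
  best <- matrix(0, nrow(out), ncol(out))
  maxpath <- numeric(length(which_labels))
  for (i in seq_along(which_labels)) {
    m <- maps[[i]]
    maxpath[i] <- max(m)
    sel <- m >= coverage_fraction * max(m) & m > 0 & m > best
    out[sel] <- which_labels[i]
    best[sel] <- m[sel]
  }
  names(maxpath) <- as.character(which_labels)
  structure(out, pixel_spacing = projection_pixel_spacing(geometry),
            geometry = geometry, max_path_mm = maxpath,
            class = c("projected_mask", "matrix", "array"))
}
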