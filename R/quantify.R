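#' Osteoporosis status from volumetric BMD
#'
#' Applies the quantitative-CT thresholds: trabecular vBMD below 80 mg/mL is
#' osteoporotic, below 120 mg/mL osteopenic, otherwise normal. Thresholds
#' are strict `<`, so a value exactly on a threshold falls in the higher
#' class.
#'
#' @param vbmd numeric vector, mg/mL; must be finite.
#' @return factor with levels osteoporotic, osteopenic, normal.
#' @examples
#' classify_status(c(79.9, 80, 150))
#' @export
classify_status <- function(vbmd) {
  if (!all(is.finite(vbmd))) stop_sdexa("vbmd must be finite")
  factor(ifelse(vbmd < 80, "osteoporotic",
                ifelse(vbmd < 120, "osteopenic", "normal")),
         levels = c("osteoporotic", "osteopenic", "normal"))
}

#' Per-vertebra volumetric BMD
#'
#' Arithmetic mean of the hydroxyapatite density over the trabecular voxels
#' of one vertebra.
#'
#' @param material a `material_volume_pair` from [decompose_image_domain()]
#'   (or any list with a `hydroxyapatite_density` array).
#' @param labels 3D integer label array (or a `labeled_volume`).
#' @param vertebra `"L1"`..`"L4"`.
#' @return vBMD in mg/mL.
#' @export
vertebra_vbmd <- function(material, labels, vertebra) {
  if (inherits(labels, "labeled_volume")) labels <- labels$labels
  code <- label_code("trabecular", vertebra)
  sel <- labels == code
  if (!any(sel)) stop_sdexa("no trabecular voxels for ", vertebra)
  mean(material$hydroxyapatite_density[sel])
}

#' Per-vertebra areal BMD
#'
#' Arithmetic mean of an aBMD map over one vertebra's 2D mask pixels. A QC
#' flag is raised when more than 20% of the mask pixels carry negative
#' aBMD (noise floor).
#'
#' @param abmd an [abmd_map()] (or plain matrix, g/cm^2).
#' @param mask2d labelled 2D mask (from [project_mask()] /
#'   [apply_transform()]).
#' @param vertebra `"L1"`..`"L4"`.
#' @return scalar g/cm^2 with attributes `mask_pixel_count` and `qc_flag`.
#' @export
vertebra_abmd <- function(abmd, mask2d, vertebra) {
  if (!identical(dim(unclass(as.matrix(abmd))), dim(unclass(as.matrix(
    mask2d))))) {
    stop_sdexa("aBMD map and 2D mask shapes differ")
  }
  code <- label_code("trabecular", vertebra)
  sel <- mask2d == code
  if (!any(sel)) stop_sdexa("mask for ", vertebra,
                            " is empty or outside the map support")
  v <- unclass(as.matrix(abmd))[sel]
  structure(mean(v), mask_pixel_count = sum(sel),
            qc_flag = mean(v < 0) > 0.2)
}

#' Build a cohort measurement table
#'
#' Quantifies per-vertebra volumetric and areal BMD for each patient of a
#' simulated cohort and assembles the tidy cohort table: one row per
#' vertebra plus one aggregate row per patient (`vertebra = "mean"`,
#' averaging L1-L4, the per-patient value used in the correlation and
#' classification analysis). Status labels derive from the measured vBMD.
#'
#' @param cohort list of patients from [generate_cohort()].
#' @param geometry the AP [scout_geometry()] used for the scout; the lateral
#'   projection uses the same geometry rotated to 90 degrees.
#' @param model an [attenuation_model()].
#' @param coverage_fraction 2D mask binarization fraction, see
#'   [project_mask()].
#' @param register logical: register the projected AP map to the measured
#'   map before applying the 2D mask (translation + affine). The simulated
#'   scout and projection share their geometry, so this defaults to FALSE
#'   for speed; [run_end_to_end()] enables it.
#' @param denoise logical: denoise the measured scout before aBMD
#'   quantification.
#' @return tibble of class `cohort_table`; columns patient_id, vertebra,
#'   vbmd_true, vbmd, abmd_measured_ap, abmd_projected_ap,
#'   abmd_projected_lateral, mask_pixel_count, qc_negative, status.
#' @export
build_cohort_table <- function(cohort, geometry, model = attenuation_model(),
                               coverage_fraction = 0.25, register = FALSE,
                               denoise = FALSE) {
  dm <- decomposition_matrix(model)
  lat_geo <- geometry
  lat_geo$view_angle <- geometry$view_angle + 90

  rows <- purrr::map_dfr(cohort, function(pat) {
    vol <- pat$volume
    mat <- decompose_image_domain(pat$monoenergetic, dm)
    vbmd_vol <- vol_from_material(mat)

    ap_abmd <- forward_project(vbmd_vol, geometry, spacing =
                                 vol$voxel_spacing)
    lat_abmd <- forward_project(vbmd_vol, lat_geo, spacing =
                                  vol$voxel_spacing)
    ap_mask <- project_mask(vol, geometry,
                            coverage_fraction = coverage_fraction)
    lat_mask <- project_mask(vol, lat_geo,
                             coverage_fraction = coverage_fraction)

    scout <- pat$scout
    if (denoise) scout <- denoise_pipeline(scout, model = model)$denoised
    meas <- epl_to_abmd(scout, model, denoised = denoise)
    meas_mask <- ap_mask
    if (register) {
      reg <- register_2d(ap_abmd, meas)
      meas_mask <- apply_transform(ap_mask, reg$transform, dim(meas))
    }

    present <- intersect(c("L1", "L2", "L3", "L4"),
                         vertebra_labels_present(vol))
    purrr::map_dfr(present, function(vb) {
      am <- vertebra_abmd(meas, meas_mask, vb)
      tibble::tibble(
        patient_id = pat$truth$patient_id,
        vertebra = vb,
        vbmd_true = pat$truth$vbmd_true,
        vbmd = vertebra_vbmd(mat, vol, vb),
        abmd_measured_ap = as.numeric(am),
        abmd_projected_ap = as.numeric(vertebra_abmd(ap_abmd, ap_mask, vb)),
        abmd_projected_lateral = as.numeric(vertebra_abmd(lat_abmd, lat_mask,
                                                          vb)),
        mask_pixel_count = attr(am, "mask_pixel_count"),
        qc_negative = attr(am, "qc_flag")
      )
    })
  })

  agg <- rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      vertebra = "mean",
      dplyr::across(c("vbmd_true", "vbmd", "abmd_measured_ap",
                      "abmd_projected_ap", "abmd_projected_lateral"), mean),
      mask_pixel_count = sum(.data$mask_pixel_count),
      qc_negative = any(.data$qc_negative),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(rows, agg) |>
    dplyr::mutate(status = classify_status(.data$vbmd)) |>
    dplyr::arrange(.data$patient_id, .data$vertebra)
  class(out) <- c("cohort_table", class(out))
  out
}

vol_from_material <- function(material) {
  material$hydroxyapatite_density / 1000   # mg/mL -> g/mL for projection
}

vertebra_labels_present <- function(volume) {
  codes <- unique(as.vector(volume$labels))
  c("L1", "L2", "L3", "L4")[c(11, 12, 13, 14) %in% codes]
}
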