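# File formats: NIfTI for volumes and 2D maps (RNifti, affine from the voxel
# spacing), JSON sidecars for metadata, CSV + JSON schema for cohort tables.

nifti_write <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr, pixdim = spacing)
  RNifti::writeNifti(img, path)
  path
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img))
}

#' Write / read a labelled phantom volume
#'
#' A `labeled_volume` is stored as three NIfTI files (water density,
#' hydroxyapatite density, labels) sharing their affine plus a JSON sidecar
#' with the label dictionary. The round trip is lossless.
#'
#' @param volume a `labeled_volume`.
#' @param prefix path prefix; files `<prefix>_water.nii.gz`,
#'   `<prefix>_ha.nii.gz`, `<prefix>_labels.nii.gz`, `<prefix>_meta.json`.
#' @return `prefix`, invisibly.
#' @export
write_labeled_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "labeled_volume"))
  sp <- volume$voxel_spacing
  nifti_write(volume$water_density, sp, paste0(prefix, "_water.nii.gz"))
  nifti_write(volume$hydroxyapatite_density, sp, paste0(prefix,
                                                        "_ha.nii.gz"))
  nifti_write(volume$labels, sp, paste0(prefix, "_labels.nii.gz"))
  jsonlite::write_json(
    list(label_dictionary = as.list(attr(volume, "label_dictionary")),
         voxel_spacing = sp),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(prefix) {
  w <- nifti_read(paste0(prefix, "_water.nii.gz"))
  h <- nifti_read(paste0(prefix, "_ha.nii.gz"))
  l <- nifti_read(paste0(prefix, "_labels.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(water_density = w$data, hydroxyapatite_density = h$data,
         labels = array(as.integer(round(l$data)), dim(l$data)),
         voxel_spacing = as.numeric(meta$voxel_spacing)),
    label_dictionary = unlist(meta$label_dictionary),
    class = "labeled_volume"
  )
}

#' Write / read a spectral projection pair
#'
#' Two 2D NIfTI images (photoelectric and Compton water-equivalent path
#' length) plus a JSON sidecar with pixel spacing and the QC record.
#'
#' @param projections a [spectral_projection_pair()].
#' @param prefix path prefix.
#' @export
write_projection_pair <- function(projections, prefix) {
  stopifnot(inherits(projections, "spectral_projection_pair"))
  sp <- as.numeric(projections$pixel_spacing)
  nifti_write(projections$photoelectric_epl, sp,
              paste0(prefix, "_photoelectric.nii.gz"))
  nifti_write(projections$compton_epl, sp, paste0(prefix,
                                                  "_compton.nii.gz"))
  jsonlite::write_json(list(pixel_spacing = sp, qc = projections$qc),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_projection_pair
#' @export
read_projection_pair <- function(prefix) {
  p <- nifti_read(paste0(prefix, "_photoelectric.nii.gz"))
  c_ <- nifti_read(paste0(prefix, "_compton.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  spectral_projection_pair(p$data, c_$data,
                           as.numeric(meta$pixel_spacing),
                           qc = as.list(meta$qc))
}

#' Write / read an areal BMD map
#'
#' One 2D NIfTI image plus JSON provenance. Maps with non-finite values are
#' rejected at write time.
#'
#' @param abmd an [abmd_map()].
#' @param prefix path prefix.
#' @export
write_abmd_map <- function(abmd, prefix) {
  stopifnot(inherits(abmd, "abmd_map"))
  if (!all(is.finite(abmd))) stop_sdexa("aBMD map contains non-finite values")
  sp <- as.numeric(attr(abmd, "pixel_spacing"))
  nifti_write(unclass(abmd), sp, paste0(prefix, "_abmd.nii.gz"))
  jsonlite::write_json(
    list(pixel_spacing = sp, provenance = attr(abmd, "provenance"),
         denoised = attr(abmd, "denoised")),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_abmd_map
#' @export
read_abmd_map <- function(prefix) {
  a <- nifti_read(paste0(prefix, "_abmd.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  abmd_map(a$data, as.numeric(meta$pixel_spacing), meta$provenance,
           denoised = isTRUE(meta$denoised))
}

cohort_schema <- function() {
  list(
    columns = list(
      patient_id = "character", vertebra = "character",
      vbmd_true = "mg/mL", vbmd = "mg/mL",
      abmd_measured_ap = "g/cm^2", abmd_projected_ap = "g/cm^2",
      abmd_projected_lateral = "g/cm^2",
      mask_pixel_count = "integer", qc_negative = "logical",
      status = "factor(osteoporotic|osteopenic|normal)"
    ),
    version = "1"
  )
}

#' Write / read a cohort table
#'
#' CSV with a JSON schema descriptor next to it; reading validates the
#' column set against the schema and names any absent column.
#'
#' @param cohort a `cohort_table` tibble.
#' @param path CSV path; the schema is written to `<path>.schema.json`.
#' @export
write_cohort_table <- function(cohort, path) {
  need <- names(cohort_schema()$columns)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop_sdexa("cohort table lacks columns: ",
               paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(cohort, path, row.names = FALSE)
  jsonlite::write_json(cohort_schema(), paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path))
  need <- names(cohort_schema()$columns)
  missing_cols <- setdiff(need, names(tb))
  if (length(missing_cols)) {
    stop_sdexa("schema mismatch, missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  tb$status <- factor(tb$status,
                      levels = c("osteoporotic", "osteopenic", "normal"))
  class(tb) <- c("cohort_table", class(tb))
  tb
}
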