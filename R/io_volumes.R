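#' CT image volume
#'
#' A 3-D scalar grid of Hounsfield-unit values together with its physical
#' geometry: voxel spacing in mm, origin in mm, and an axis-orientation code
#' (RNifti-style three-letter string, e.g. `"RAS"`). Volumes loaded from disk
#' are reoriented to the canonical `"RAS"` convention; the on-disk orientation
#' is recorded in `source_orientation`. All reported volumes are
#' orientation-invariant, so the reorientation never changes a result.
#'
#' @param data 3-D numeric array of HU values. Must be finite everywhere.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm; physical position of the first voxel.
#' @param orientation three-letter axis code; default `"RAS"`.
#' @param source_orientation orientation of the file the volume came from,
#'   if different.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = "RAS", source_orientation = orientation) {
  if (!is.array(data) || length(dim(data)) != 3L)
    pf_stop("pulmofat_input_error", "volume data must be a 3-D array")
  if (any(dim(data) < 1L))
    pf_stop("pulmofat_input_error", "every volume dimension must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    pf_stop("pulmofat_input_error",
            "spacing must be 3 strictly positive finite values (mm)")
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    pf_stop("pulmofat_io_error", "volume contains ", nbad,
            " non-finite (NaN/Inf) voxel(s)")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         orientation = orientation, source_orientation = source_orientation),
    class = "ct_volume"
  )
}

#' Label mask on a CT grid
#'
#' Integer labels on the same geometry as a [ct_volume()]: 0 is always
#' background, positive integers are anatomical labels. The default lobe
#' convention is `c(LUL = 1, LLL = 2, RUL = 3, RML = 4, RLL = 5)` and a
#' combined lung mask uses label 1.
#'
#' @param data 3-D array of non-negative integers.
#' @param spacing,origin,orientation,source_orientation as in [ct_volume()].
#' @param label_map named integer vector mapping anatomical names to labels.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = "RAS", source_orientation = orientation,
                       label_map = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    pf_stop("pulmofat_input_error", "mask data must be a 3-D array")
  if (anyNA(data) || any(!is.finite(data)))
    pf_stop("pulmofat_io_error", "mask contains non-finite values")
  if (any(data < 0) || any(data != round(data)))
    pf_stop("pulmofat_input_error",
            "mask labels must be non-negative integers")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    pf_stop("pulmofat_input_error",
            "spacing must be 3 strictly positive finite values (mm)")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         orientation = orientation, source_orientation = source_orientation,
         label_map = label_map),
    class = "label_mask"
  )
}

#' Default pulmonary-lobe label convention
#'
#' @return Named integer vector `c(LUL = 1, LLL = 2, RUL = 3, RML = 4, RLL = 5)`.
#' @export
default_lobe_labels <- function() {
  c(LUL = 1L, LLL = 2L, RUL = 3L, RML = 4L, RLL = 5L)
}

canonical_orientation <- "RAS"

nifti_to_parts <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) pf_stop("pulmofat_io_error",
                    "cannot read NIfTI file '", path, "': ", conditionMessage(e)))
  if (length(dim(img)) == 4L && dim(img)[4] == 1L)
    img <- RNifti::asNifti(array(img, dim = dim(img)[1:3]), reference = img)
  if (length(dim(img)) != 3L)
    pf_stop("pulmofat_io_error", "'", path, "' is not a 3-D volume (dims: ",
            paste(dim(img), collapse = "x"), ")")
  src <- RNifti::orientation(img)
  if (!identical(src, canonical_orientation)) {
    ok <- tryCatch({ RNifti::orientation(img) <- canonical_orientation; TRUE },
                   warning = function(w) FALSE)
    if (!ok) src <- canonical_orientation  # no usable xform: take as canonical
  }
  aff <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = as.numeric(RNifti::pixdim(img))[1:3],
       origin = as.numeric(aff[1:3, 4]),
       source_orientation = src)
}

#' Load a CT volume
#'
#' Reads a NIfTI file or a DICOM series directory into a [ct_volume()] in
#' Hounsfield units. For DICOM the rescale slope/intercept are applied
#' (`HU = slope * stored + intercept`); files missing the rescale tags are
#' rejected rather than silently assumed to be identity. Volumes are
#' reoriented to the canonical `"RAS"` axis convention on load.
#'
#' @param path a NIfTI file (`.nii`/`.nii.gz`) or a directory containing one
#'   coherent DICOM series.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or
#'   `"dicom_series"`.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (!file.exists(path))
    pf_stop("pulmofat_io_error", "path does not exist: '", path, "'")
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "dicom_series") return(load_dicom_series(path))
  p <- nifti_to_parts(path)
  nbad <- sum(!is.finite(p$data))
  if (nbad > 0L)
    pf_stop("pulmofat_io_error", "'", path, "' contains ", nbad,
            " non-finite (NaN/Inf) voxel(s)")
  ct_volume(p$data, p$spacing, p$origin,
            orientation = canonical_orientation,
            source_orientation = p$source_orientation)
}

#' Load a label mask
#'
#' As [load_volume()] but validates that values are non-negative integers and
#' returns a [label_mask()].
#'
#' @inheritParams load_volume
#' @param label_map optional named integer vector naming the labels.
#' @return A [label_mask()].
#' @export
load_mask <- function(path, label_map = NULL) {
  if (!file.exists(path))
    pf_stop("pulmofat_io_error", "path does not exist: '", path, "'")
  p <- nifti_to_parts(path)
  if (any(!is.finite(p$data)))
    pf_stop("pulmofat_io_error", "mask '", path, "' contains non-finite voxels")
  if (any(p$data != round(p$data)) || any(p$data < 0))
    pf_stop("pulmofat_io_error", "mask '", path,
            "' contains non-integer or negative labels")
  label_mask(p$data, p$spacing, p$origin,
             orientation = canonical_orientation,
             source_orientation = p$source_orientation,
             label_map = label_map)
}

write_nifti_parts <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) pf_stop("pulmofat_io_error",
             "cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Write a label mask to NIfTI
#'
#' `load_mask(write_mask(m, path))` is the identity on data and geometry.
#'
#' @param mask a [label_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  write_nifti_parts(mask$data, mask$spacing, mask$origin, path)
}

#' Write a CT volume to NIfTI
#'
#' @param volume a [ct_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  write_nifti_parts(volume$data, volume$spacing, volume$origin, path)
}

#' Check that an image and a mask share one voxel grid
#'
#' Quantification is only meaningful when the mask annotates exactly the
#' image's grid, so shapes must be equal, spacing componentwise within
#' `tol_mm` (default 1e-4 mm, which absorbs header float noise without
#' admitting real mismatches) and orientations identical. No resampling is
#' ever attempted: a mismatch is a hard refusal downstream, because silent
#' resampling changes volumes — the quantity under study.
#'
#' @param image a [ct_volume()].
#' @param mask a [label_mask()].
#' @param tol_mm spacing tolerance in mm.
#' @return A list of class `geometry_report` with `shape_match`,
#'   `spacing_delta` (per-axis, mm), `orientation_match` and
#'   `verdict` (`"pass"`/`"fail"`).
#' @export
validate_geometry <- function(image, mask, tol_mm = 1e-4) {
  stopifnot(inherits(image, "ct_volume"), inherits(mask, "label_mask"))
  shape_match <- identical(dim(image$data), dim(mask$data))
  spacing_delta <- abs(image$spacing - mask$spacing)
  spacing_match <- all(spacing_delta <= tol_mm)
  orientation_match <- identical(image$orientation, mask$orientation)
  verdict <- if (shape_match && spacing_match && orientation_match)
    "pass" else "fail"
  structure(
    list(shape_match = shape_match, spacing_delta = spacing_delta,
         spacing_match = spacing_match,
         orientation_match = orientation_match, verdict = verdict),
    class = "geometry_report"
  )
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Geometry check:", x$verdict, "\n")
  cat("  shape match:      ", x$shape_match, "\n")
  cat("  spacing delta mm: ", paste(signif(x$spacing_delta, 4), collapse = ", "),
      "\n")
  cat("  orientation match:", x$orientation_match, "\n")
  invisible(x)
}

assert_geometry <- function(image, mask, what = "mask") {
  rep <- validate_geometry(image, mask)
  if (rep$verdict != "pass")
    pf_stop("pulmofat_geometry_error", "image and ", what,
            " are not on the same grid (shape match: ", rep$shape_match,
            ", max spacing delta: ", signif(max(rep$spacing_delta), 4),
            " mm, orientation match: ", rep$orientation_match,
            "); refusing to resample")
  invisible(rep)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume:", paste(dim(x$data), collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm spacing,",
      "HU range [", signif(min(x$data), 4), ",", signif(max(x$data), 4), "]\n")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- sort(unique(as.integer(x$data)))
  cat("Label mask:", paste(dim(x$data), collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm spacing, labels:",
      paste(labs, collapse = ", "), "\n")
  invisible(x)
}
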