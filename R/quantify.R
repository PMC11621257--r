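#' Fat attenuation window
#'
#' Closed Hounsfield-unit interval defining "fat-isodense". The default is
#' \[-200, -60\] HU; both endpoints are included. The bounds are exposed
#' because the literature also uses \[-200, -40\].
#'
#' @param lower,upper finite HU bounds, `lower < upper`.
#' @return An object of class `hu_window`.
#' @export
hu_window <- function(lower = -200, upper = -60) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    pf_stop("pulmofat_input_error",
            "HU window must satisfy lower < upper with finite bounds")
  structure(list(lower = lower, upper = upper), class = "hu_window")
}

#' @export
print.hu_window <- function(x, ...) {
  cat("HU window: [", x$lower, ",", x$upper, "] (closed)\n")
  invisible(x)
}

in_window <- function(hu, window) hu >= window$lower & hu <= window$upper

#' Physical volume of one voxel
#'
#' @param spacing numeric length-3, mm per voxel.
#' @return Voxel volume in mL (mm^3 / 1000).
#' @export
voxel_volume_ml <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    pf_stop("pulmofat_input_error", "spacing must be 3 positive values (mm)")
  prod(spacing) / 1000
}

binary_lung <- function(lung, lung_label = NULL) {
  if (is.null(lung_label)) lung$data > 0L else lung$data %in% lung_label
}

#' Extract fat-isodense voxels inside the lung
#'
#' A voxel is fat iff it lies in the lung mask and its HU value is inside the
#' closed window (both endpoints inclusive). Voxels spanning tissue
#' interfaces are counted wholly in or out by their HU value — no sub-voxel
#' weighting — so partial-volume effects are reported, not corrected.
#'
#' @param image a [ct_volume()].
#' @param lung a [label_mask()]; any positive label counts as lung unless
#'   `lung_label` selects specific labels.
#' @param window a [hu_window()].
#' @param lung_label optional label(s) to treat as lung.
#' @return Binary [label_mask()] (1 = fat) on the image geometry.
#' @export
threshold_fat <- function(image, lung, window = hu_window(),
                          lung_label = NULL) {
  stopifnot(inherits(image, "ct_volume"), inherits(lung, "label_mask"),
            inherits(window, "hu_window"))
  assert_geometry(image, lung, "lung mask")
  inlung <- binary_lung(lung, lung_label)
  if (!any(inlung))
    pf_stop("pulmofat_input_error",
            "lung mask is empty: fat quantification and PFI are undefined")
  fat <- array(0L, dim = dim(image$data))
  fat[inlung & in_window(image$data, window)] <- 1L
  label_mask(fat, image$spacing, image$origin, image$orientation,
             label_map = c(fat = 1L))
}

#' Pulmonary fat index from volumes
#'
#' `PFI = 100 * CTpfav / lung volume` (percent).
#'
#' @param ctpfav_ml fat attenuation volume, mL.
#' @param lung_volume_ml lung volume, mL; must be positive.
#' @return PFI in percent.
#' @export
compute_pfi <- function(ctpfav_ml, lung_volume_ml) {
  if (!is.finite(lung_volume_ml) || lung_volume_ml <= 0)
    pf_stop("pulmofat_input_error",
            "PFI is undefined for non-positive lung volume (",
            lung_volume_ml, " mL)")
  if (!is.finite(ctpfav_ml) || ctpfav_ml < 0 || ctpfav_ml > lung_volume_ml)
    pf_stop("pulmofat_input_error", "CTpfav (", ctpfav_ml,
            " mL) must lie in [0, lung volume] = [0, ", lung_volume_ml, "]")
  100 * ctpfav_ml / lung_volume_ml
}

new_fat_quant <- function(fat_n, lung_n, vox_ml, window) {
  ctpfav <- fat_n * vox_ml
  lungvol <- lung_n * vox_ml
  structure(
    list(ctpfav_ml = ctpfav, lung_volume_ml = lungvol,
         pfi_pct = if (lung_n > 0L) 100 * ctpfav / lungvol else NA_real_,
         fat_voxel_count = fat_n, lung_voxel_count = lung_n,
         voxel_volume_ml = vox_ml, window = window),
    class = "fat_quant"
  )
}

#' Quantify pulmonary fat attenuation volume and PFI
#'
#' Counts lung voxels and fat-isodense lung voxels (per [threshold_fat()]),
#' converts counts to physical volumes via the voxel volume, and derives the
#' pulmonary fat index `PFI = 100 * CTpfav / lung volume`.
#'
#' @inheritParams threshold_fat
#' @return An object of class `fat_quant` with fields `ctpfav_ml`,
#'   `lung_volume_ml`, `pfi_pct`, `fat_voxel_count`, `lung_voxel_count`,
#'   `voxel_volume_ml` and `window`.
#' @export
compute_ctpfav <- function(image, lung, window = hu_window(),
                           lung_label = NULL) {
  stopifnot(inherits(image, "ct_volume"), inherits(lung, "label_mask"),
            inherits(window, "hu_window"))
  assert_geometry(image, lung, "lung mask")
  inlung <- binary_lung(lung, lung_label)
  lung_n <- sum(inlung)
  if (lung_n == 0L)
    pf_stop("pulmofat_input_error",
            "lung mask is empty: fat quantification and PFI are undefined")
  fat_n <- sum(inlung & in_window(image$data, window))
  new_fat_quant(fat_n, lung_n, voxel_volume_ml(image$spacing), window)
}

# Quantify over an arbitrary logical region; empty regions are allowed and
# reported with zero counts and an NA PFI (used for compartments, where one
# side of a partition may legitimately be empty).
quant_region <- function(image, region, window) {
  fat_n <- sum(region & in_window(image$data, window))
  new_fat_quant(fat_n, sum(region), voxel_volume_ml(image$spacing), window)
}

#' @export
print.fat_quant <- function(x, ...) {
  cat(sprintf("CTpfav: %.4f mL (%d voxels)\n", x$ctpfav_ml, x$fat_voxel_count))
  cat(sprintf("Lung volume: %.4f mL (%d voxels)\n",
              x$lung_volume_ml, x$lung_voxel_count))
  cat(sprintf("PFI: %s %%  [window %g..%g HU]\n",
              ifelse(is.na(x$pfi_pct), "NA", sprintf("%.4f", x$pfi_pct)),
              x$window$lower, x$window$upper))
  invisible(x)
}

fat_quant_fields <- function(x, prefix = "") {
  out <- list(ctpfav_ml = x$ctpfav_ml, lung_volume_ml = x$lung_volume_ml,
              pfi_pct = x$pfi_pct, fat_voxel_count = x$fat_voxel_count,
              lung_voxel_count = x$lung_voxel_count,
              voxel_volume_ml = x$voxel_volume_ml)
  if (nzchar(prefix)) names(out) <- paste0(prefix, "_", names(out))
  out
}
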