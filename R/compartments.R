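#' Signed Euclidean distance map of a binary mask
#'
#' Exact voxel-centre-to-voxel-centre Euclidean distances in physical mm,
#' honouring anisotropic spacing (separable lower-envelope transform, not a
#' chamfer approximation). Sign convention: negative inside the mask
#' (magnitude = distance to the nearest background voxel centre), positive
#' outside (distance to the nearest mask voxel centre).
#'
#' @param mask a binary [label_mask()] (any positive label is foreground).
#' @return An object of class `distance_map`: `data` (3-D array, mm),
#'   `spacing`, `origin`, `orientation`.
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  fg <- mask$data > 0L
  nfg <- sum(fg)
  if (nfg == 0L || nfg == length(fg))
    pf_stop("pulmofat_input_error",
            "mask is entirely ", if (nfg == 0L) "background" else "foreground",
            ": its boundary, and hence the distance map, is undefined")
  dims <- dim(fg)
  d2_to_bg <- cpp_edt_squared(as.logical(!fg), dims, mask$spacing)
  d2_to_fg <- cpp_edt_squared(as.logical(fg), dims, mask$spacing)
  sgn <- array(ifelse(fg, -sqrt(d2_to_bg), sqrt(d2_to_fg)), dim = dims)
  structure(
    list(data = sgn, spacing = mask$spacing, origin = mask$origin,
         orientation = mask$orientation),
    class = "distance_map"
  )
}

#' @export
print.distance_map <- function(x, ...) {
  cat("Signed distance map:", paste(dim(x$data), collapse = " x "),
      "voxels, range [", signif(min(x$data), 4), ",", signif(max(x$data), 4),
      "] mm\n")
  invisible(x)
}

#' Partition the lung into subpleural and nonsubpleural compartments
#'
#' A lung voxel is subpleural iff its distance to the lung-mask boundary is
#' at most `depth_mm` (closed condition: boundary voxels are subpleural).
#' The reference surface is the entire boundary of the merged binary lung
#' mask — costal, mediastinal, diaphragmatic and hilar alike — never lobe
#' fissures. The two output masks are an exact disjoint partition of the
#' lung.
#'
#' @param lung binary [label_mask()] of the (merged) lung.
#' @param depth_mm compartment depth in mm; default 10 (1 cm).
#' @return List with binary masks `subpleural` and `nonsubpleural`, the
#'   `distance_map`, and `depth_mm`.
#' @export
subpleural_partition <- function(lung, depth_mm = 10) {
  stopifnot(inherits(lung, "label_mask"))
  if (!is.finite(depth_mm) || depth_mm <= 0)
    pf_stop("pulmofat_input_error", "depth_mm must be positive")
  dm <- signed_distance(lung)
  fg <- lung$data > 0L
  sub <- fg & (-dm$data <= depth_mm)
  nonsub <- fg & !sub
  mk <- function(sel, nm) {
    m <- array(0L, dim = dim(fg)); m[sel] <- 1L
    label_mask(m, lung$spacing, lung$origin, lung$orientation,
               label_map = stats::setNames(1L, nm))
  }
  list(subpleural = mk(sub, "subpleural"),
       nonsubpleural = mk(nonsub, "nonsubpleural"),
       distance_map = dm, depth_mm = depth_mm)
}

#' Fat quantification per subpleural/nonsubpleural compartment
#'
#' Runs the fat-window quantification separately on the subpleural and
#' nonsubpleural compartments of the lung. Voxel counts and CTpfav of the
#' two compartments sum exactly to the whole-lung values. An empty
#' compartment (e.g. depth exceeding the lung inradius) is reported with
#' zero volume and `NA` PFI.
#'
#' @inheritParams compute_ctpfav
#' @param depth_mm subpleural depth in mm (default 10).
#' @return Object of class `compartment_quant`: `subpleural` and
#'   `nonsubpleural` (each a `fat_quant`), `whole` and `depth_mm`.
#' @export
compartment_quant <- function(image, lung, window = hu_window(),
                              depth_mm = 10, lung_label = NULL) {
  stopifnot(inherits(image, "ct_volume"), inherits(lung, "label_mask"))
  assert_geometry(image, lung, "lung mask")
  inlung <- binary_lung(lung, lung_label)
  if (!any(inlung))
    pf_stop("pulmofat_input_error", "lung mask is empty")
  bin <- label_mask(array(as.integer(inlung), dim = dim(inlung)),
                    lung$spacing, lung$origin, lung$orientation)
  part <- subpleural_partition(bin, depth_mm)
  structure(
    list(subpleural = quant_region(image, part$subpleural$data > 0L, window),
         nonsubpleural = quant_region(image, part$nonsubpleural$data > 0L,
                                      window),
         whole = quant_region(image, inlung, window),
         depth_mm = depth_mm),
    class = "compartment_quant"
  )
}

#' @export
print.compartment_quant <- function(x, ...) {
  cat("Subpleural compartment (depth", x$depth_mm, "mm):\n")
  print(x$subpleural)
  cat("Nonsubpleural compartment:\n")
  print(x$nonsubpleural)
  invisible(x)
}

lobe_groups <- list(upper = c("LUL", "RUL"), middle = "RML",
                    lower = c("LLL", "RLL"))

#' Per-lobe and per-lobe-group fat quantification
#'
#' Quantifies fat in each pulmonary lobe present in the lobe mask and
#' aggregates lobes into the groups upper = LUL+RUL, middle = RML,
#' lower = LLL+RLL. Group PFI uses pooled voxel counts
#' (`100 * sum(CTpfav) / sum(lung volume)`), never the mean of lobe PFIs, so
#' group values respect the PFI formula on the pooled region. Lobes need not
#' tile the lung (incomplete fissures); lobes absent from the mask are
#' omitted, not reported as zero.
#'
#' @inheritParams compute_ctpfav
#' @param lobes [label_mask()] with lobe labels.
#' @param label_map named integer vector naming lobe labels; defaults to
#'   [default_lobe_labels()].
#' @return Object of class `lobar_quant`: `per_lobe` (named list of
#'   `fat_quant`) and `per_group` (named list of `fat_quant`).
#' @export
lobar_quant <- function(image, lobes, window = hu_window(),
                        label_map = NULL) {
  stopifnot(inherits(image, "ct_volume"), inherits(lobes, "label_mask"))
  assert_geometry(image, lobes, "lobe mask")
  label_map <- label_map %||% lobes$label_map %||% default_lobe_labels()
  present <- sort(setdiff(unique(as.integer(lobes$data)), 0L))
  unknown <- setdiff(present, label_map)
  if (length(unknown) > 0L)
    pf_stop("pulmofat_input_error", "lobe mask contains label(s) ",
            paste(unknown, collapse = ", "), " not in the label map (",
            paste(names(label_map), label_map, sep = "=", collapse = ", "), ")")
  vox_ml <- voxel_volume_ml(image$spacing)
  per_lobe <- list()
  for (nm in names(label_map)) {
    lab <- label_map[[nm]]
    if (!(lab %in% present)) next
    per_lobe[[nm]] <- quant_region(image, lobes$data == lab, window)
  }
  per_group <- list()
  for (g in names(lobe_groups)) {
    members <- intersect(lobe_groups[[g]], names(per_lobe))
    if (length(members) == 0L) next
    fat_n <- sum(vapply(per_lobe[members], `[[`, 0L, "fat_voxel_count"))
    lung_n <- sum(vapply(per_lobe[members], `[[`, 0L, "lung_voxel_count"))
    per_group[[g]] <- new_fat_quant(fat_n, lung_n, vox_ml, window)
  }
  structure(list(per_lobe = per_lobe, per_group = per_group, window = window),
            class = "lobar_quant")
}

#' @export
print.lobar_quant <- function(x, ...) {
  for (nm in names(x$per_lobe))
    cat(sprintf("%-4s ctpfav %8.4f mL  lung %10.4f mL  PFI %s %%\n", nm,
                x$per_lobe[[nm]]$ctpfav_ml, x$per_lobe[[nm]]$lung_volume_ml,
                format(x$per_lobe[[nm]]$pfi_pct, digits = 4)))
  for (nm in names(x$per_group))
    cat(sprintf("[%s] ctpfav %8.4f mL  lung %10.4f mL  PFI %s %%\n", nm,
                x$per_group[[nm]]$ctpfav_ml, x$per_group[[nm]]$lung_volume_ml,
                format(x$per_group[[nm]]$pfi_pct, digits = 4)))
  invisible(x)
}
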