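# Synthetic chest-CT phantom: two ellipsoidal "lungs" filled with aerated
# parenchyma, planar lobe cuts, optional vessel cylinders and fat-isodense
# spheres of analytically known volume. Rasterization is by voxel-centre
# inclusion, so every ground-truth count has a provable surface-error bound.

# --- analytic geometry -------------------------------------------------------

# Distance from points (rows of p, mm) to the surface of an axis-aligned
# ellipsoid, via the Lagrange condition sum(a_i^2 y_i^2/(a_i^2+t)^2) = 1,
# whose largest root (monotone in t on (-min a^2, Inf)) identifies the
# nearest surface point; solved by vectorized bisection. Valid for interior
# and exterior points alike.
ellipsoid_surface_distance <- function(p, center, semi_axes) {
  p <- matrix(p, ncol = 3)
  y <- sweep(p, 2, center)
  y[abs(y) < 1e-9] <- 1e-9            # degenerate on-axis points: nudge
  a2 <- semi_axes^2
  lo <- rep(-min(a2) * (1 - 1e-12), nrow(y))
  # t is in mm^2; this upper bracket guarantees f(hi) < 0
  hi <- 2 * max(semi_axes) * (sqrt(rowSums(y^2)) + max(semi_axes))
  f <- function(t) {
    s <- 0
    for (i in 1:3) s <- s + a2[i] * y[, i]^2 / (a2[i] + t)^2
    s - 1
  }
  # f(hi) < 0 guaranteed by construction of hi; f(lo) > 0 by the nudge
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t <- (lo + hi) / 2
  dd <- y
  for (i in 1:3) dd[, i] <- y[, i] * t / (a2[i] + t)
  sqrt(rowSums(dd^2))
}

inside_ellipsoid <- function(p, center, semi_axes) {
  p <- matrix(p, ncol = 3)
  s <- 0
  for (i in 1:3) s <- s + ((p[, i] - center[i]) / semi_axes[i])^2
  s <= 1
}

# Distance from interior points of the lung union to the union surface:
# minimum of the per-ellipsoid surface distances (valid when the two
# ellipsoids are disjoint, which the spec validation enforces).
lung_surface_distance <- function(p, lung_geometry) {
  pmin(ellipsoid_surface_distance(p, lung_geometry$left$center,
                                  lung_geometry$left$semi_axes),
       ellipsoid_surface_distance(p, lung_geometry$right$center,
                                  lung_geometry$right$semi_axes))
}

default_lung_geometry <- function(grid_shape, spacing) {
  ext <- grid_shape * spacing
  list(left = list(center = c(0.25, 0.5, 0.5) * ext,
                   semi_axes = c(0.14, 0.26, 0.34) * ext),
       right = list(center = c(0.75, 0.5, 0.5) * ext,
                    semi_axes = c(0.14, 0.26, 0.34) * ext))
}

#' Specification of a synthetic chest-CT phantom
#'
#' Describes a deterministic phantom: grid and spacing, two ellipsoidal
#' lungs, planar lobe cuts along the z (cranio-caudal) axis, parenchyma and
#' soft-tissue attenuation, optional vessel cylinders, and fat spheres of
#' analytically known volume. Fat can be given explicitly (`fat`) or as a
#' request (`fat_request`) that [generate_phantom()] resolves by seeded
#' rejection sampling under a placement constraint.
#'
#' Defaults emulate aerated parenchyma at -850 +/- 30 HU (far below the fat
#' window), soft tissue at +40 HU (far above it), vessels at +50 HU and fat
#' inclusions at -100 HU.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel.
#' @param lung_geometry list with `left` and `right`, each
#'   `list(center, semi_axes)` in mm; default fills the grid with two
#'   disjoint ellipsoids.
#' @param lobe_plan `list(left_cut_frac, right_cut_fracs)`: fractional z
#'   cuts (of each lung's z extent, from caudal) separating LLL/LUL and
#'   RLL/RML/RUL.
#' @param parenchyma_hu `c(mean, sd)` of lung parenchyma HU.
#' @param soft_tissue_hu HU of everything outside the lungs.
#' @param vessels list of cylinders `list(p1, p2, radius_mm, hu)`.
#' @param fat list of spheres `list(center, radius_mm, hu)`.
#' @param fat_request `list(n | target_ml, radius_mm, placement, hu)`;
#'   `placement` is `NULL` or `list(type, value)` with type one of
#'   `"subpleural_within_mm"`, `"deeper_than_mm"`, `"lobe"`.
#' @param noise_sd i.i.d. Gaussian HU noise added after tissue assignment.
#' @param seed integer RNG seed; same spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = c(1, 1, 1),
                         lung_geometry = NULL,
                         lobe_plan = list(left_cut_frac = 0.55,
                                          right_cut_fracs = c(0.45, 0.75)),
                         parenchyma_hu = c(mean = -850, sd = 30),
                         soft_tissue_hu = 40,
                         vessels = list(), fat = list(), fat_request = NULL,
                         noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    pf_stop("pulmofat_input_error", "grid_shape must be 3 integers >= 4")
  if (length(spacing) != 3L || any(spacing <= 0))
    pf_stop("pulmofat_input_error", "spacing must be 3 positive mm values")
  lung_geometry <- lung_geometry %||% default_lung_geometry(grid_shape, spacing)
  # disjoint lungs: conservative bounding-box check
  l <- lung_geometry$left; r <- lung_geometry$right
  if (all(abs(l$center - r$center) < l$semi_axes + r$semi_axes))
    pf_stop("pulmofat_input_error", "lung ellipsoids must be disjoint")
  pm <- unname(parenchyma_hu[1]); ps <- unname(parenchyma_hu[2])
  w <- hu_window()
  tot_sd <- sqrt(ps^2 + noise_sd^2)
  if (pm + 4 * tot_sd > w$lower)
    pf_stop("pulmofat_input_error", "parenchyma HU (", pm, " +/- ", tot_sd,
            ") is not at least 4 sd below the fat window lower bound (",
            w$lower, "); false fat voxels would not be rare")
  if (soft_tissue_hu - 4 * noise_sd < w$upper)
    pf_stop("pulmofat_input_error", "soft tissue HU (", soft_tissue_hu,
            ") is not at least 4 noise sd above the fat window upper bound")
  structure(
    list(grid_shape = grid_shape, spacing = spacing,
         lung_geometry = lung_geometry, lobe_plan = lobe_plan,
         parenchyma_hu = c(mean = pm, sd = ps),
         soft_tissue_hu = soft_tissue_hu, vessels = vessels, fat = fat,
         fat_request = fat_request, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

voxel_centers_axis <- function(n, h) (seq_len(n) - 0.5) * h

# label lungs and lobes by voxel-centre inclusion; returns integer arrays
rasterize_lungs <- function(spec) {
  gs <- spec$grid_shape; sp <- spec$spacing
  cx <- voxel_centers_axis(gs[1], sp[1])
  cy <- voxel_centers_axis(gs[2], sp[2])
  cz <- voxel_centers_axis(gs[3], sp[3])
  enorm2 <- function(e) {
    tx <- ((cx - e$center[1]) / e$semi_axes[1])^2
    ty <- ((cy - e$center[2]) / e$semi_axes[2])^2
    tz <- ((cz - e$center[3]) / e$semi_axes[3])^2
    outer(outer(tx, ty, "+"), tz, "+")
  }
  left <- enorm2(spec$lung_geometry$left) <= 1
  right <- enorm2(spec$lung_geometry$right) <= 1
  lung <- left | right
  zarr <- aperm(array(rep(cz, each = gs[1] * gs[2]), dim = gs), c(1, 2, 3))
  lobes <- array(0L, dim = gs)
  lg <- spec$lung_geometry
  zcut <- function(e, frac) (e$center[3] - e$semi_axes[3]) +
    frac * 2 * e$semi_axes[3]
  lcut <- zcut(lg$left, spec$lobe_plan$left_cut_frac)
  rc <- vapply(spec$lobe_plan$right_cut_fracs, zcut, 0, e = lg$right)
  labs <- default_lobe_labels()
  lobes[left & zarr <= lcut] <- labs[["LLL"]]
  lobes[left & zarr > lcut] <- labs[["LUL"]]
  lobes[right & zarr <= rc[1]] <- labs[["RLL"]]
  lobes[right & zarr > rc[1] & zarr <= rc[2]] <- labs[["RML"]]
  lobes[right & zarr > rc[2]] <- labs[["RUL"]]
  list(lung = lung, lobes = lobes, cx = cx, cy = cy, cz = cz)
}

# voxel-centre membership mask of one sphere, restricted to its bounding box
sphere_voxels <- function(sph, cx, cy, cz) {
  ix <- which(abs(cx - sph$center[1]) <= sph$radius_mm)
  iy <- which(abs(cy - sph$center[2]) <= sph$radius_mm)
  iz <- which(abs(cz - sph$center[3]) <= sph$radius_mm)
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
  d2 <- outer(outer((cx[ix] - sph$center[1])^2, (cy[iy] - sph$center[2])^2,
                    "+"), (cz[iz] - sph$center[3])^2, "+")
  sel <- which(d2 <= sph$radius_mm^2, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(NULL)
  cbind(ix[sel[, 1]], iy[sel[, 2]], iz[sel[, 3]])
}

lobe_of_point <- function(p, spec) {
  lg <- spec$lung_geometry
  zcut <- function(e, frac) (e$center[3] - e$semi_axes[3]) +
    frac * 2 * e$semi_axes[3]
  if (inside_ellipsoid(p, lg$left$center, lg$left$semi_axes)) {
    if (p[3] <= zcut(lg$left, spec$lobe_plan$left_cut_frac)) "LLL" else "LUL"
  } else if (inside_ellipsoid(p, lg$right$center, lg$right$semi_axes)) {
    rc <- vapply(spec$lobe_plan$right_cut_fracs, zcut, 0, e = lg$right)
    if (p[3] <= rc[1]) "RLL" else if (p[3] <= rc[2]) "RML" else "RUL"
  } else NA_character_
}

# seeded rejection sampling of non-overlapping fat spheres under an optional
# placement constraint, checked against the analytic lung surface distance
place_fat_spheres <- function(spec, radii, placement = NULL, hu = -100,
                              existing = list(), max_tries_per = 2000) {
  lg <- spec$lung_geometry
  bb_lo <- pmin(lg$left$center - lg$left$semi_axes,
                lg$right$center - lg$right$semi_axes)
  bb_hi <- pmax(lg$left$center + lg$left$semi_axes,
                lg$right$center + lg$right$semi_axes)
  placed <- existing
  for (r in radii) {
    ok <- FALSE
    for (try in seq_len(max_tries_per)) {
      p <- bb_lo + runif(3) * (bb_hi - bb_lo)
      if (!inside_ellipsoid(p, lg$left$center, lg$left$semi_axes) &&
          !inside_ellipsoid(p, lg$right$center, lg$right$semi_axes)) next
      d <- lung_surface_distance(p, lg)
      if (d < r + 1e-6) next                       # sphere must fit inside
      if (!is.null(placement)) {
        if (placement$type == "subpleural_within_mm") {
          if (d + r > placement$value) next
        } else if (placement$type == "deeper_than_mm") {
          if (d - r <= placement$value) next
        } else if (placement$type == "lobe") {
          if (!identical(lobe_of_point(p, spec), placement$value)) next
        } else {
          pf_stop("pulmofat_input_error", "unknown placement type '",
                  placement$type, "'")
        }
      }
      clash <- FALSE
      for (s in placed) {
        if (sqrt(sum((p - s$center)^2)) <= r + s$radius_mm + 1e-9) {
          clash <- TRUE; break
        }
      }
      if (clash) next
      placed <- c(placed, list(list(center = p, radius_mm = r, hu = hu)))
      ok <- TRUE
      break
    }
    if (!ok)
      pf_stop("pulmofat_input_error", "could not place a fat sphere of ",
              "radius ", signif(r, 4), " mm after ", max_tries_per,
              " attempts; the placement constraint is infeasible")
  }
  placed
}

resolve_fat_request <- function(spec, lung_voxel_ml) {
  rq <- spec$fat_request
  r0 <- rq$radius_mm %||% 3
  hu <- rq$hu %||% -100
  v0 <- 4 / 3 * pi * r0^3 / 1000
  if (!is.null(rq$target_ml)) {
    n_full <- floor(rq$target_ml / v0)
    radii <- rep(r0, n_full)
    rem <- rq$target_ml - n_full * v0
    if (rem > 1e-9) radii <- c(radii, (3 * rem * 1000 / (4 * pi))^(1 / 3))
  } else {
    radii <- rep(r0, rq$n %||% 1)
  }
  place_fat_spheres(spec, radii, placement = rq$placement, hu = hu,
                    existing = spec$fat)
}

validate_fat_set <- function(fat, spec) {
  if (length(fat) < 2L) {
    for (s in fat)
      if (lung_surface_distance(s$center, spec$lung_geometry) < s$radius_mm -
          1e-9 ||
          (!inside_ellipsoid(s$center, spec$lung_geometry$left$center,
                             spec$lung_geometry$left$semi_axes) &&
           !inside_ellipsoid(s$center, spec$lung_geometry$right$center,
                             spec$lung_geometry$right$semi_axes)))
        pf_stop("pulmofat_input_error",
                "fat sphere does not lie inside the lung geometry")
    return(invisible(TRUE))
  }
  for (i in seq_along(fat)) {
    s <- fat[[i]]
    inl <- inside_ellipsoid(s$center, spec$lung_geometry$left$center,
                            spec$lung_geometry$left$semi_axes) ||
      inside_ellipsoid(s$center, spec$lung_geometry$right$center,
                       spec$lung_geometry$right$semi_axes)
    if (!inl || lung_surface_distance(s$center, spec$lung_geometry) <
        s$radius_mm - 1e-9)
      pf_stop("pulmofat_input_error",
              "fat sphere ", i, " does not lie inside the lung geometry")
    for (j in seq_len(i - 1L)) {
      t <- fat[[j]]
      if (sqrt(sum((s$center - t$center)^2)) < s$radius_mm + t$radius_mm)
        pf_stop("pulmofat_input_error", "fat spheres ", j, " and ", i,
                " overlap; overlapping spheres break the analytic volume")
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic chest-CT phantom
#'
#' Rasterizes a [phantom_spec()] into an HU image, a binary lung mask and a
#' lobe mask (voxel-centre inclusion), and computes geometric ground truth —
#' analytic fat volume `sum(4/3 pi r^3)`, voxelized fat/lung volumes, and
#' per-lobe / per-compartment fat breakdowns — by direct evaluation of the
#' shape equations, entirely independent of the HU-threshold quantifier.
#' Identical spec + seed yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param depth_mm subpleural depth used for the ground-truth compartment
#'   split (analytic surface distance), default 10.
#' @return Object of class `ct_phantom`: `image` ([ct_volume()]), `lung` and
#'   `lobes` ([label_mask()]), `truth` (list), `spec` (with resolved fat).
#' @export
generate_phantom <- function(spec, depth_mm = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  ras <- rasterize_lungs(spec)
  gs <- spec$grid_shape
  img <- array(spec$soft_tissue_hu, dim = gs)
  nlung <- sum(ras$lung)
  img[ras$lung] <- rnorm(nlung, spec$parenchyma_hu[["mean"]],
                         spec$parenchyma_hu[["sd"]])

  for (v in spec$vessels) {
    # cylinder p1-p2 radius: point-to-segment distance on the bounding box
    lo <- pmin(v$p1, v$p2) - v$radius_mm
    hi <- pmax(v$p1, v$p2) + v$radius_mm
    ix <- which(ras$cx >= lo[1] & ras$cx <= hi[1])
    iy <- which(ras$cy >= lo[2] & ras$cy <= hi[2])
    iz <- which(ras$cz >= lo[3] & ras$cz <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- as.matrix(expand.grid(x = ras$cx[ix], y = ras$cy[iy], z = ras$cz[iz]))
    ax <- v$p2 - v$p1
    t <- pmin(1, pmax(0, (sweep(g, 2, v$p1) %*% ax) / sum(ax^2)))
    d2 <- rowSums((g - (rep(1, nrow(g)) %o% v$p1 + t %*% t(ax)))^2)
    idx <- as.matrix(expand.grid(ix, iy, iz))[d2 <= v$radius_mm^2, ,
                                              drop = FALSE]
    if (nrow(idx)) img[idx] <- v$hu %||% 50
  }

  vox_ml <- voxel_volume_ml(spec$spacing)
  fat <- spec$fat
  if (!is.null(spec$fat_request))
    fat <- resolve_fat_request(spec, vox_ml)
  validate_fat_set(fat, spec)

  fat_idx <- NULL
  for (s in fat) {
    vv <- sphere_voxels(s, ras$cx, ras$cy, ras$cz)
    if (is.null(vv)) next
    img[vv] <- s$hu %||% -100
    fat_idx <- rbind(fat_idx, vv)
  }
  if (!is.null(fat_idx)) fat_idx <- unique(fat_idx)  # overlap forbidden anyway

  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = gs)

  # ground truth from geometry only (never from HU values)
  n_fat <- if (is.null(fat_idx)) 0L else nrow(fat_idx)
  truth <- list(
    fat_volume_ml_analytic = sum(vapply(fat, function(s)
      4 / 3 * pi * s$radius_mm^3, 0)) / 1000,
    fat_voxel_count = n_fat,
    fat_volume_ml_voxelized = n_fat * vox_ml,
    lung_voxel_count = nlung,
    lung_volume_ml_voxelized = nlung * vox_ml,
    depth_mm = depth_mm
  )
  if (n_fat > 0L) {
    centers <- cbind(ras$cx[fat_idx[, 1]], ras$cy[fat_idx[, 2]],
                     ras$cz[fat_idx[, 3]])
    d <- lung_surface_distance(centers, spec$lung_geometry)
    truth$fat_volume_ml_subpleural <- sum(d <= depth_mm) * vox_ml
    truth$fat_volume_ml_nonsubpleural <- sum(d > depth_mm) * vox_ml
    lobe_lab <- ras$lobes[fat_idx]
    labs <- default_lobe_labels()
    truth$fat_volume_ml_per_lobe <- vapply(labs, function(l)
      sum(lobe_lab == l) * vox_ml, 0)
  } else {
    truth$fat_volume_ml_subpleural <- 0
    truth$fat_volume_ml_nonsubpleural <- 0
    truth$fat_volume_ml_per_lobe <- vapply(default_lobe_labels(),
                                           function(l) 0, 0)
  }

  spec$fat <- fat
  spec$fat_request <- NULL
  structure(
    list(image = ct_volume(img, spec$spacing),
         lung = label_mask(array(as.integer(ras$lung), dim = gs),
                           spec$spacing, label_map = c(lung = 1L)),
         lobes = label_mask(ras$lobes, spec$spacing,
                            label_map = default_lobe_labels()),
         truth = truth, spec = spec),
    class = "ct_phantom"
  )
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat("Synthetic CT phantom:", paste(x$spec$grid_shape, collapse = " x "),
      "voxels @", paste(signif(x$spec$spacing, 4), collapse = " x "), "mm\n")
  cat(sprintf("  lung %.2f mL, fat (analytic) %.4f mL, fat (voxelized) %.4f mL, %d fat sphere(s)\n",
              x$truth$lung_volume_ml_voxelized, x$truth$fat_volume_ml_analytic,
              x$truth$fat_volume_ml_voxelized, length(x$spec$fat)))
  invisible(x)
}

#' Write phantom image and masks to a directory
#'
#' @param phantom a `ct_phantom`.
#' @param dir output directory (created if needed). Writes `image.nii.gz`,
#'   `lung.nii.gz`, `lobes.nii.gz` and `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ct_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$image, file.path(dir, "image.nii.gz"))
  write_mask(phantom$lung, file.path(dir, "lung.nii.gz"))
  write_mask(phantom$lobes, file.path(dir, "lobes.nii.gz"))
  jsonlite::write_json(phantom$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
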