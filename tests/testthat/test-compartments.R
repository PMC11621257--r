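cube_mask <- function(n = 30, pad = 2, spacing = c(1, 1, 1)) {
  dims <- rep(n + 2 * pad, 3)
  arr <- array(0L, dim = dims)
  arr[pad + (1:n), pad + (1:n), pad + (1:n)] <- 1L
  label_mask(arr, spacing = spacing)
}

test_that("interior distances match brute force on a cube", {
  m <- cube_mask(30)
  dm <- signed_distance(m)
  o <- oracle_interior_distance(m$data > 0L, m$spacing)
  expect_equal(-dm$data[o$fg], o$distance, tolerance = 1e-9)
  # centre voxel of a 30-cube is 15 voxel steps from background
  ctr <- rep(2 + 15, 3)
  expect_equal(dm$data[ctr[1], ctr[2], ctr[3]], -15)
  # sign convention: mask voxels <= 0, background >= 0
  expect_true(all(dm$data[m$data > 0L] <= 0))
  expect_true(all(dm$data[m$data == 0L] >= 0))
})

test_that("a single mask voxel sits within one spacing of the boundary", {
  arr <- array(0L, dim = c(21, 21, 21))
  arr[11, 11, 11] <- 1L
  dm <- signed_distance(label_mask(arr, spacing = c(0.8, 1, 2)))
  expect_equal(dm$data[11, 11, 11], -0.8)
  expect_lte(abs(dm$data[11, 11, 11]), max(c(0.8, 1, 2)))
})

test_that("anisotropic slab distances are in mm, not voxels", {
  arr <- array(0L, dim = c(12, 12, 9))
  arr[3:10, 3:10, 4:6] <- 1L               # 3 voxels thick along z
  m <- label_mask(arr, spacing = c(1, 1, 3))
  dm <- signed_distance(m)
  o <- oracle_interior_distance(arr > 0L, m$spacing)
  expect_equal(-dm$data[o$fg], o$distance, tolerance = 1e-9)
  # mid-slab voxel (6,6,5): the z route to background is 2 slices = 6 mm,
  # so the 4 mm in-plane route wins — mm, not voxel counts
  expect_equal(dm$data[6, 6, 5], -4)
})

test_that("empty and full masks are rejected", {
  expect_error(signed_distance(label_mask(array(0L, dim = c(4, 4, 4)))),
               class = "pulmofat_input_error")
  expect_error(signed_distance(label_mask(array(1L, dim = c(4, 4, 4)))),
               class = "pulmofat_input_error")
})

test_that("cube partition at 10 mm leaves the inner 10^3 core nonsubpleural", {
  m <- cube_mask(30)
  part <- subpleural_partition(m, depth_mm = 10)
  expect_equal(sum(part$nonsubpleural$data), 1000L)
  expect_equal(sum(part$subpleural$data), 27000L - 1000L)
  # exact disjoint partition
  expect_equal(part$subpleural$data + part$nonsubpleural$data,
               m$data)
})

test_that("partition labels match brute-force search on random masks", {
  set.seed(42)
  cases <- list(list(dims = c(24, 24, 24), sp = c(1, 1, 1), depth = 5),
                list(dims = c(32, 28, 20), sp = c(1, 1, 2.5), depth = 6),
                list(dims = c(20, 20, 20), sp = c(0.7, 0.7, 1.5), depth = 4))
  for (cs in cases) {
    for (rep in 1:3) {
      mask <- random_blob_mask(cs$dims, cs$sp)
      if (!any(mask)) next
      m <- label_mask(array(as.integer(mask), dim = cs$dims), spacing = cs$sp)
      part <- subpleural_partition(m, depth_mm = cs$depth)
      oracle_sub <- oracle_subpleural_labels(mask, cs$sp, cs$depth)
      expect_identical(part$subpleural$data > 0L, oracle_sub)
    }
  }
})

test_that("disjoint lung components partition as they would alone", {
  dims <- c(40, 16, 16)
  arr <- array(0L, dim = dims)
  arr[3:10, 5:12, 5:12] <- 1L
  arr[28:38, 4:13, 4:13] <- 1L              # > depth apart from the first
  m <- label_mask(arr, spacing = c(1, 1, 1))
  part <- subpleural_partition(m, depth_mm = 3)
  for (xr in list(3:10, 28:38)) {
    solo <- array(0L, dim = dims)
    solo[xr, , ] <- arr[xr, , ]
    ps <- subpleural_partition(label_mask(solo), depth_mm = 3)
    expect_identical(part$subpleural$data[xr, , ],
                     ps$subpleural$data[xr, , ])
  }
})

test_that("subpleural voxel count is monotone in depth", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                      spacing = c(2, 2, 2)))
  counts <- vapply(c(2, 5, 10, 15, 25, 60), function(d)
    sum(subpleural_partition(ph$lung, d)$subpleural$data), 0L)
  expect_true(all(diff(counts) >= 0))
  # saturation: depth beyond the inradius puts the whole lung subpleural
  expect_equal(counts[length(counts)], sum(ph$lung$data))
  expect_equal(sum(subpleural_partition(ph$lung, 60)$nonsubpleural$data), 0L)
})

test_that("scaling spacing and depth together preserves the voxel partition", {
  set.seed(9)
  mask <- random_blob_mask(c(20, 20, 20), c(1, 1, 1))
  m1 <- label_mask(array(as.integer(mask), dim = c(20, 20, 20)))
  m2 <- label_mask(array(as.integer(mask), dim = c(20, 20, 20)),
                   spacing = c(2.5, 2.5, 2.5))
  p1 <- subpleural_partition(m1, depth_mm = 4)
  p2 <- subpleural_partition(m2, depth_mm = 10)
  expect_identical(p1$subpleural$data, p2$subpleural$data)
})

test_that("compartment quantification conserves counts and volumes", {
  ph <- generate_phantom(single_sphere_spec(noise_sd = 10, seed = 2))
  cq <- compartment_quant(ph$image, ph$lung, depth_mm = 10)
  expect_identical(cq$subpleural$lung_voxel_count +
                     cq$nonsubpleural$lung_voxel_count,
                   cq$whole$lung_voxel_count)
  expect_identical(cq$subpleural$fat_voxel_count +
                     cq$nonsubpleural$fat_voxel_count,
                   cq$whole$fat_voxel_count)
  expect_lt(abs(cq$subpleural$ctpfav_ml + cq$nonsubpleural$ctpfav_ml -
                  cq$whole$ctpfav_ml), 1e-9)
})

test_that("fat placed shallow or deep lands in the expected compartment", {
  shallow <- generate_phantom(phantom_spec(
    fat_request = list(n = 4, radius_mm = 2,
                       placement = list(type = "subpleural_within_mm",
                                        value = 5)),
    seed = 8))
  cq <- compartment_quant(shallow$image, shallow$lung, depth_mm = 10)
  expect_equal(cq$nonsubpleural$ctpfav_ml, 0)
  expect_gt(cq$subpleural$ctpfav_ml, 0)

  # rounder lungs so a 15 mm-deep core exists (default min semi-axis ~13 mm)
  round_geom <- list(
    left = list(center = c(30, 48, 48), semi_axes = c(20, 28, 34)),
    right = list(center = c(72, 48, 48), semi_axes = c(20, 28, 34)))
  deep <- generate_phantom(phantom_spec(
    lung_geometry = round_geom,
    fat_request = list(n = 3, radius_mm = 2,
                       placement = list(type = "deeper_than_mm", value = 15)),
    seed = 8))
  cqd <- compartment_quant(deep$image, deep$lung, depth_mm = 10)
  expect_equal(cqd$subpleural$ctpfav_ml, 0)
  expect_gt(cqd$nonsubpleural$ctpfav_ml, 0)
})

test_that("uniformly scattered fat gives similar PFI in both compartments", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  set.seed(4)
  lung_idx <- which(ph$lung$data > 0L)
  img <- ph$image$data
  img[sample(lung_idx, round(0.05 * length(lung_idx)))] <- -100
  cq <- compartment_quant(ct_volume(img, ph$image$spacing), ph$lung)
  rel <- abs(cq$subpleural$pfi_pct - cq$nonsubpleural$pfi_pct) /
    cq$subpleural$pfi_pct
  expect_lt(rel, 0.2)
})

test_that("lobar quantification pools groups and flags unknown labels", {
  # fat only in the two lower lobes
  ph <- generate_phantom(phantom_spec(
    fat_request = list(n = 2, radius_mm = 3,
                       placement = list(type = "lobe", value = "LLL")),
    seed = 6))
  ph2 <- generate_phantom(phantom_spec(
    fat = c(ph$spec$fat,
            list(list(center = c(72, 48, 24), radius_mm = 3, hu = -100))),
    seed = 6))
  lq <- lobar_quant(ph2$image, ph2$lobes)
  expect_gt(lq$per_group$lower$ctpfav_ml, 0)
  expect_equal(lq$per_group$upper$ctpfav_ml, 0)
  expect_equal(lq$per_group$middle$ctpfav_ml, 0)
  # group PFI is pooled, not a mean of lobe PFIs
  expect_equal(lq$per_group$lower$pfi_pct,
               100 * (lq$per_lobe$LLL$ctpfav_ml + lq$per_lobe$RLL$ctpfav_ml) /
                 (lq$per_lobe$LLL$lung_volume_ml +
                    lq$per_lobe$RLL$lung_volume_ml))

  # single-lobe mask: other groups absent, not zero
  single <- ph2$lobes
  single$data[single$data != 2L] <- 0L
  lqs <- lobar_quant(ph2$image, single)
  expect_named(lqs$per_lobe, "LLL")
  expect_named(lqs$per_group, "lower")

  bad <- ph2$lobes
  bad$data[1, 1, 1] <- 9L
  expect_error(lobar_quant(ph2$image, bad), "label",
               class = "pulmofat_input_error")
})
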