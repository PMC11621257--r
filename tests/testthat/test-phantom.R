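test_that("identical spec and seed give bit-identical phantoms", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), noise_sd = 20, seed = 33,
                       fat = list(list(center = c(10, 20, 20),
                                       radius_mm = 4, hu = -100)))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$lung$data, b$lung$data)
  expect_identical(a$lobes$data, b$lobes$data)
  expect_identical(a$truth, b$truth)
})

test_that("seeds change the noise field but never the masks", {
  mk <- function(seed) generate_phantom(phantom_spec(
    grid_shape = c(40, 40, 40), noise_sd = 20, seed = seed))
  a <- mk(1); b <- mk(2)
  expect_identical(a$lung$data, b$lung$data)
  expect_identical(a$lobes$data, b$lobes$data)
  expect_false(identical(a$image$data, b$image$data))
})

test_that("ground truth bounds hold: analytic vs voxelized fat volume", {
  ph <- generate_phantom(single_sphere_spec())
  tr <- ph$truth
  expect_equal(tr$fat_volume_ml_analytic, 4 / 3 * pi * 10^3 / 1000)
  expect_lt(abs(tr$fat_volume_ml_analytic - tr$fat_volume_ml_voxelized) /
              tr$fat_volume_ml_analytic, 0.02)
  expect_equal(tr$fat_volume_ml_voxelized,
               tr$fat_voxel_count * voxel_volume_ml(ph$image$spacing))
  # compartment and lobe ground truths are partitions of the fat volume
  expect_equal(tr$fat_volume_ml_subpleural + tr$fat_volume_ml_nonsubpleural,
               tr$fat_volume_ml_voxelized)
  expect_equal(sum(tr$fat_volume_ml_per_lobe), tr$fat_volume_ml_voxelized)
})

test_that("generator ground truth agrees with the quantifier (two routes)", {
  # agreement of the HU-threshold route with the geometric route; noise at
  # sd 20 pushes ~2% of fat voxels (HU -100) past the -60 bound, so the
  # comparison allows for that loss
  ph <- generate_phantom(single_sphere_spec(noise_sd = 20, seed = 12))
  q <- compute_ctpfav(ph$image, ph$lung)
  expect_equal(q$ctpfav_ml, ph$truth$fat_volume_ml_voxelized,
               tolerance = 0.05)
  expect_lte(q$ctpfav_ml, ph$truth$fat_volume_ml_voxelized)
  expect_equal(q$lung_volume_ml, ph$truth$lung_volume_ml_voxelized)
})

test_that("overlapping or out-of-lung fat spheres are rejected", {
  expect_error(generate_phantom(phantom_spec(
    fat = list(list(center = c(24, 48, 48), radius_mm = 5, hu = -100),
               list(center = c(27, 48, 48), radius_mm = 5, hu = -100)))),
    "overlap", class = "pulmofat_input_error")
  expect_error(generate_phantom(phantom_spec(
    fat = list(list(center = c(48, 48, 48), radius_mm = 3, hu = -100)))),
    class = "pulmofat_input_error")    # centre lies between the lungs
  expect_error(generate_phantom(phantom_spec(
    fat = list(list(center = c(24, 48, 48), radius_mm = 20, hu = -100)))),
    class = "pulmofat_input_error")    # pokes through the surface
})

test_that("tissue attenuations too close to the fat window are rejected", {
  expect_error(phantom_spec(parenchyma_hu = c(mean = -300, sd = 30)),
               class = "pulmofat_input_error")
  expect_error(phantom_spec(soft_tissue_hu = -70),   # inside the window
               class = "pulmofat_input_error")
  expect_error(phantom_spec(noise_sd = 40),   # soft tissue 40 - 4*40 < -60
               class = "pulmofat_input_error")
})

test_that("infeasible placement constraints fail with an explicit error", {
  expect_error(generate_phantom(phantom_spec(
    fat_request = list(n = 1, radius_mm = 2,
                       placement = list(type = "deeper_than_mm",
                                        value = 40)))),
    "infeasible", class = "pulmofat_input_error")
})

test_that("placement constraints are honoured against the distance map", {
  ph <- generate_phantom(phantom_spec(
    fat_request = list(n = 5, radius_mm = 2,
                       placement = list(type = "subpleural_within_mm",
                                        value = 6)),
    seed = 21))
  dm <- signed_distance(ph$lung)
  fat_vox <- ph$image$data >= -200 & ph$image$data <= -60 & ph$lung$data > 0L
  # analytic constraint plus rasterization slack of one voxel diagonal
  expect_lte(max(-dm$data[fat_vox]), 6 + sqrt(3))
})

test_that("phantom directory output round trips", {
  d <- tempfile()
  ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24), seed = 2))
  write_phantom(ph, d)
  expect_true(all(file.exists(file.path(
    d, c("image.nii.gz", "lung.nii.gz", "lobes.nii.gz",
         "ground_truth.json")))))
  img <- load_volume(file.path(d, "image.nii.gz"))
  expect_equal(img$data, ph$image$data, tolerance = 1e-12)
  lungs <- load_mask(file.path(d, "lung.nii.gz"))
  expect_identical(lungs$data, ph$lung$data)
  unlink(d, recursive = TRUE)
})

test_that("cohort simulation is reproducible and respects its targets", {
  sim1 <- generate_cohort(n_per_group = 2, seed = 5,
                          template = phantom_spec(grid_shape = c(48, 48, 48),
                                                  spacing = c(2, 2, 2)))
  sim2 <- generate_cohort(n_per_group = 2, seed = 5,
                          template = phantom_spec(grid_shape = c(48, 48, 48),
                                                  spacing = c(2, 2, 2)))
  expect_identical(sim1$table, sim2$table)
  expect_equal(nrow(sim1$table), 6L)
  expect_setequal(unique(sim1$table$group), c("control", "COPD", "fILD"))
  # constructed fat matches the sampled target within voxelization error
  expect_true(all(abs(sim1$table$fat_volume_ml_truth -
                        sim1$table$pfi_target_pct / 100 *
                        sim1$table$lung_volume_ml) /
                    pmax(sim1$table$fat_volume_ml_truth, 0.01) < 0.25))
})

test_that("one subject per group yields a three-row table", {
  sim <- generate_cohort(n_per_group = 1, seed = 9,
                         template = phantom_spec(grid_shape = c(48, 48, 48),
                                                 spacing = c(2, 2, 2)))
  expect_equal(nrow(sim$table), 3L)
})
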