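# ct_segmentation module: preprocessing, multilevel classing, shive and
# hyphae extraction, apparent volume, solid fraction

test_that("preprocessing zeroes background and keeps objects exactly (noiseless)", {
  # all-zero volume
  z <- voxel_volume(array(0, c(24, 24, 8)), 1)
  out <- preprocess_volume(z, segmentation_params(adaptive_window_um = 10))
  expect_true(all(out$values == 0))

  # two-level phantom: object 200, background 10 -> exact separation
  arr <- array(10, c(40, 40, 12))
  arr[12:28, 12:28, ] <- 200
  v <- voxel_volume(arr, 1)
  out <- preprocess_volume(v, segmentation_params(adaptive_window_um = 16))
  expect_true(all(out$values[arr == 200] == 200))
  expect_true(all(out$values[arr == 10] == 0))
})

test_that("preprocessing suppresses noisy background", {
  set.seed(1)
  arr <- array(60, c(48, 48, 16))
  arr[16:32, 16:32, ] <- 220
  truth_bg <- arr == 60
  arr <- pmin(pmax(arr + rnorm(length(arr), 0, 10), 0), 255)
  v <- voxel_volume(array(arr, c(48, 48, 16)), 1.41)
  out <- preprocess_volume(v, segmentation_params())
  expect_gte(mean(out$values[truth_bg] == 0), 0.99)
  expect_gte(mean(out$values[!truth_bg] > 0), 0.99)
})

test_that("window larger than the slice is a config error", {
  v <- voxel_volume(array(runif(10 * 10 * 4), c(10, 10, 4)), 1)
  expect_error(preprocess_volume(v, segmentation_params(adaptive_window_um = 100)),
               class = "mycomat_config")
})

test_that("multilevel Otsu separates well-separated populations exactly", {
  set.seed(2)
  arr <- array(0, c(30, 30, 3))
  arr[] <- sample(c(60, 140, 220), length(arr), replace = TRUE)
  v <- voxel_volume(arr, 1)
  cls <- multilevel_classes(v, segmentation_params())
  expect_true(all(cls[arr == 60] == 1L))
  expect_true(all(cls[arr == 140] == 2L))
  expect_true(all(cls[arr == 220] == 3L))

  # degenerate histogram errors loudly
  two <- voxel_volume(array(rep(c(0, 50, 90), length.out = 2700), c(30, 30, 3)), 1)
  two$values[two$values == 90] <- 50
  expect_error(multilevel_classes(two, segmentation_params()),
               class = "mycomat_degenerate_histogram")
})

test_that("rendered phantom classes agree with truth at the stated noise", {
  w <- small_phantom(8)
  vol <- render_grayscale(w$truth, w$cfg)
  masked <- preprocess_volume(vol, segmentation_params())
  cls <- multilevel_classes(masked, segmentation_params())
  pred <- ifelse(cls == 3L, 2L, ifelse(cls == 2L, 1L, 0L))
  agree <- mean(pred == w$truth$labels)
  expect_gte(agree, 0.98)
})

test_that("shive size rule keeps 216000 um3 and drops 125000 um3 objects", {
  arr <- array(0L, c(80, 80, 80))
  arr[2:61, 2:61, 2:61] <- 3L   # 60^3 = 216000 um3 at 1 um voxels
  v <- voxel_volume(array(60, dim(arr)), 1)
  sh <- extract_shive_mask(arr, v, segmentation_params())
  expect_identical(max(sh$labels), 1L)
  expect_identical(sum(sh$solid_mask), 216000L)

  arr2 <- array(0L, c(80, 80, 80))
  arr2[2:51, 2:51, 2:51] <- 3L  # 50^3 = 125000 um3 < 140000
  sh2 <- extract_shive_mask(arr2, v, segmentation_params())
  expect_identical(sum(sh2$solid_mask), 0L)

  sh3 <- extract_shive_mask(array(0L, c(8, 8, 8)),
                            voxel_volume(array(0, c(8, 8, 8)), 1),
                            segmentation_params())
  expect_false(any(sh3$solid_mask))
})

test_that("size filters in um3 match a brute-force voxel-count oracle", {
  set.seed(3)
  mask <- array(runif(24 * 24 * 24) > 0.9, c(24, 24, 24))
  vox <- 1.7
  thresh_um3 <- 40
  sizes <- brute_component_sizes(mask)
  expected_kept_voxels <- sum(sizes[sizes >= ceiling(thresh_um3 / vox^3)])
  cls <- array(0L, dim(mask)); cls[mask] <- 1L
  v <- voxel_volume(array(0, dim(mask)), vox)
  sh <- extract_shive_mask(cls, v, segmentation_params(shive_min_volume_um3 = thresh_um3))
  expect_identical(sum(sh$solid_mask), expected_kept_voxels)
})

test_that("apparent mask fills channels and is identity on convex slabs", {
  solid <- array(FALSE, c(10, 40, 40)); solid[, , 12:28] <- TRUE
  for (y in 1:40) for (z in 1:40)
    if ((y - 20)^2 + (z - 20)^2 <= 16) solid[, y, z] <- FALSE
  sh <- shive_segmentation_from_masks(solid, 1)
  sh <- compute_apparent_mask(sh, segmentation_params(closing_radius_um = 6),
                              slice_axis = 1)
  full <- array(FALSE, c(10, 40, 40)); full[, , 12:28] <- TRUE
  expect_identical(sh$apparent_mask, full)
  expect_true(all(!sh$solid_mask | sh$apparent_mask)) # solid ⊆ apparent

  convex <- array(FALSE, c(3, 30, 30)); convex[, 10:22, 8:22] <- TRUE
  shc <- compute_apparent_mask(shive_segmentation_from_masks(convex, 1),
                               segmentation_params(closing_radius_um = 4),
                               slice_axis = 1)
  expect_identical(shc$apparent_mask, convex)

  she <- compute_apparent_mask(shive_segmentation_from_masks(array(FALSE, c(4, 20, 20)), 1),
                               segmentation_params(closing_radius_um = 3))
  expect_false(any(she$apparent_mask))
  expect_error(compute_apparent_mask(shive_segmentation_from_masks(convex, 1),
                                     segmentation_params(closing_radius_um = 20)),
               class = "mycomat_config")
})

test_that("solid fraction and apparent density follow the voxel counts", {
  solid <- array(TRUE, c(10, 10, 10))
  sh <- shive_segmentation_from_masks(solid, 1, apparent_mask = solid)
  sh <- shive_solid_fraction(sh)
  expect_identical(sh$epsilon_substrate, 1)

  # constructed counts: 100 x 100 x 10 slab with exactly 20000 pore voxels
  ap <- array(TRUE, c(100, 100, 10))
  so <- ap; so[seq_len(20000)] <- FALSE
  sh2 <- shive_solid_fraction(shive_segmentation_from_masks(so, 1.41, ap))
  expect_equal(sh2$epsilon_substrate, 0.8, tolerance = 1e-12)
  expect_equal(sh2$apparent_density_kg_m3, 0.8 * 1450, tolerance = 1e-12)

  expect_error(shive_solid_fraction(shive_segmentation_from_masks(
    array(FALSE, c(4, 4, 4)), 1, array(FALSE, c(4, 4, 4)))),
    class = "mycomat_no_substrate")
})

test_that("hyphae extraction removes sub-280-um3 objects and empty remainders warn", {
  # isolated bright blob of 90 voxels at 1.41 um voxels: 252 um3 < 280 um3
  arr <- array(60, c(40, 40, 40))
  blob <- as.matrix(expand.grid(x = 10:12, y = 10:14, z = 10:15))[1:90, ]
  arr[blob] <- 200
  v <- voxel_volume(arr, 1.41)
  sh <- shive_segmentation_from_masks(array(FALSE, dim(arr)), 1.41)
  hy <- extract_hyphae_mask(v, sh, segmentation_params())
  expect_identical(sum(hy$mask), 0L)

  # same blob above threshold (101 voxels = 283 um3) is kept
  arr2 <- array(60, c(40, 40, 40))
  blob2 <- as.matrix(expand.grid(x = 10:12, y = 10:14, z = 10:16))[1:101, ]
  arr2[blob2] <- 200
  hy2 <- extract_hyphae_mask(voxel_volume(arr2, 1.41), sh, segmentation_params())
  expect_identical(sum(hy2$mask), 101L)
  expect_equal(hy2$V_hyphae_um3, 101 * 1.41^3, tolerance = 1e-12)

  flat <- voxel_volume(array(7, c(10, 10, 10)), 1.41)
  expect_warning(hy3 <- extract_hyphae_mask(flat, shive_segmentation_from_masks(
    array(FALSE, c(10, 10, 10)), 1.41), segmentation_params()))
  expect_identical(hy3$V_hyphae_um3, 0)
})

test_that("full pipeline: empty input, determinism, mask invariants", {
  zero <- voxel_volume(array(0, c(32, 32, 32)), 1.41, slice_axis = 1)
  r0 <- run_segmentation_pipeline(zero)
  expect_false(any(r0$shive$solid_mask))
  expect_false(any(r0$hyphae$mask))

  w <- small_phantom(9)
  vol <- render_grayscale(w$truth, w$cfg)
  r1 <- run_segmentation_pipeline(vol)
  r2 <- run_segmentation_pipeline(vol)
  expect_identical(r1$shive$solid_mask, r2$shive$solid_mask)
  expect_identical(r1$hyphae$mask, r2$hyphae$mask)
  # disjointness and inclusion invariants
  expect_false(any(r1$hyphae$mask & r1$shive$solid_mask))
  expect_true(all(!r1$shive$solid_mask | r1$shive$apparent_mask))
  expect_true(r1$shive$epsilon_substrate >= 0 && r1$shive$epsilon_substrate <= 1)
  expect_equal(r1$shive$V_solid_um3, sum(r1$shive$solid_mask) * 1.41^3,
               tolerance = 1e-9)
  expect_equal(r1$shive$apparent_density_kg_m3,
               r1$shive$epsilon_substrate * 1450, tolerance = 1e-12)
  # recovery on this seed
  expect_lt(abs(r1$shive$epsilon_substrate - w$truth$true_solid_fraction), 0.03)
  expect_gt(dice_of(r1$hyphae$mask, w$truth$labels == 1L), 0.9)
})
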