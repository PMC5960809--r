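test_that("NIfTI write/read round trip preserves voxels, spacing, origin", {
  set.seed(1)
  vox <- array(round(rnorm(10 * 12 * 14, 40, 20), 2), c(10, 12, 14))
  v <- volume_hu(vox, spacing = c(1.5, 0.8, 0.8), origin = c(-4, 2, 7))
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  v2 <- read_volume(tf)
  expect_equal(dim(v2$voxels), dim(v$voxels))
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-7)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
})

test_that("phantom volume survives the NIfTI round trip exactly in shape and grid", {
  g <- generate_control(phantom_spec(shape = c(40, 64, 64),
                                     spacing = c(1, 1, 1),
                                     skull_semi = c(16, 28, 26),
                                     skull_thick = 4), seed = 3)
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(g$volume, tf)
  v2 <- read_volume(tf)
  expect_equal(dim(v2$voxels), c(40L, 64L, 64L))
  expect_equal(v2$spacing, c(1, 1, 1))
  expect_lt(max(abs(v2$voxels - g$volume$voxels)), 1e-3)
})

test_that("non-3-D and malformed inputs are rejected with diagnostics", {
  expect_error(read_volume(tempfile()), "not found")
  tf <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(64), 8, 8)), tf)
  expect_error(read_volume(tf), "3-D")
  expect_error(volume_hu(array(1, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(volume_hu(array(c(NA, rep(1, 7)), c(2, 2, 2)), c(1, 1, 1)),
               "finite")
})

test_that("axial resampling is exact for no-ops, constants and linear ramps", {
  v <- volume_hu(array(rnorm(8 * 6 * 6), c(8, 6, 6)), c(1, 1, 1))
  expect_identical(resample_axial(v, 1)$voxels, v$voxels)

  cst <- volume_hu(array(7.5, c(9, 5, 5)), c(2, 1, 1))
  r <- resample_axial(cst, 1.2)
  expect_lt(max(abs(r$voxels - 7.5)), 1e-8)
  expect_equal(r$spacing[1], 1.2)

  # 2 mm slices holding an axial linear ramp -> 1 mm reconstruction must
  # reproduce the analytic ramp at the new slice positions
  nz <- 11
  ramp <- volume_hu(array(rep(3 * (0:(nz - 1)) * 2 + 5, 4 * 4),
                          c(nz, 4, 4)), c(2, 1, 1), origin = c(10, 0, 0))
  r1 <- resample_axial(ramp, 1)
  zpos <- r1$origin[1] + (seq_len(dim(r1$voxels)[1]) - 1) * 1
  expected <- 3 * (zpos - 10) + 5
  expect_lt(max(abs(sweep(r1$voxels, 1, expected))), 1e-6)
  # physical extent preserved to within one slice
  expect_lte(abs(max(zpos) - (10 + (nz - 1) * 2)), 1)
  expect_error(resample_axial(ramp, 1000), "extent")
})

test_that("slice cropping keeps exactly the bone-bearing range and is idempotent", {
  spec <- phantom_spec(shape = c(30, 48, 48), spacing = c(2, 2, 2),
                       skull_semi = c(20, 36, 30), skull_thick = 5,
                       noise_sd = 0)
  g <- generate_control(spec, 2)
  vox <- g$volume$voxels
  pad <- array(-1000, c(5, dim(vox)[2], dim(vox)[3]))
  padded <- volume_hu(abind_slices(pad, vox, pad), g$volume$spacing,
                      g$volume$origin - c(5 * 2, 0, 0))
  cropped <- crop_irrelevant_slices(padded)
  bone <- apply(vox > 300, 1, any)
  expect_equal(dim(cropped$voxels)[1], sum(seq_along(bone) >= which(bone)[1] &
                                             seq_along(bone) <= max(which(bone))))
  # physical coordinates of retained voxels unchanged
  expect_equal(cropped$origin[1],
               padded$origin[1] + (5 + which(bone)[1] - 1) * 2)
  expect_identical(crop_irrelevant_slices(cropped)$voxels, cropped$voxels)
  expect_error(crop_irrelevant_slices(
    volume_hu(array(-1000, c(4, 4, 4)), c(1, 1, 1))), "no skull")
})

test_that("external structures are stripped, the head is untouched, and the op is idempotent", {
  spec <- phantom_spec(shape = c(30, 56, 48), spacing = c(2, 2, 2),
                       skull_semi = c(20, 36, 30), skull_thick = 5,
                       clutter = TRUE, noise_sd = 0)
  g <- generate_control(spec, 4)
  vol <- g$volume
  pillow <- vol$voxels > 35 & vol$voxels < 45  # 40 HU slab + gray ribbon
  st <- strip_externals(vol)
  # all pillow voxels outside the mask became air
  outside40 <- which(!st$mask & abs(vol$voxels - 40) < 1e-9)
  expect_gt(length(outside40), 0)  # the pillow existed
  expect_true(all(st$volume$voxels[outside40] == -1000))
  # voxels inside the mask are untouched
  expect_identical(st$volume$voxels[st$mask], vol$voxels[st$mask])
  # idempotence
  st2 <- strip_externals(st$volume)
  expect_identical(st2$volume$voxels, st$volume$voxels)

  # phantom with no externals: inside-head voxels unchanged
  spec2 <- phantom_spec(shape = c(30, 48, 48), spacing = c(2, 2, 2),
                        skull_semi = c(20, 32, 28), skull_thick = 5,
                        clutter = FALSE, noise_sd = 0)
  v2 <- generate_control(spec2, 5)$volume
  st3 <- strip_externals(v2)
  head <- v2$voxels > -200
  expect_identical(st3$volume$voxels[head], v2$voxels[head])
  expect_true(all(st3$mask[head]))
  expect_error(strip_externals(
    volume_hu(array(-1000, c(4, 4, 4)), c(1, 1, 1))), "head")
})

test_that("connectivity ties resolve to the component nearest the volume centre", {
  vox <- array(-1000, c(11, 21, 11))
  vox[5:7, 9:12, 5:7] <- 50    # central blob, 36 voxels
  vox[5:7, 1:4, 5:7] <- 50     # equal-size peripheral blob
  v <- volume_hu(vox, c(1, 1, 1))
  st <- strip_externals(v, close_mm = 0)
  expect_true(all(st$volume$voxels[5:7, 9:12, 5:7] == 50))
  expect_true(all(st$volume$voxels[5:7, 1:4, 5:7] == -1000))
})
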