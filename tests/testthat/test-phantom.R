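spec0 <- phantom_spec(shape = c(36, 52, 48), spacing = c(2, 2, 2),
                      skull_semi = c(26, 40, 34), skull_thick = 5,
                      noise_sd = 0)

test_that("control phantoms are deterministic and vary across seeds", {
  a <- generate_control(spec0, 11)
  b <- generate_control(spec0, 11)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$landmarks, b$landmarks)
  c <- generate_control(spec0, 12)
  head <- a$volume$voxels > -200 | c$volume$voxels > -200
  expect_gt(mean(abs(a$volume$voxels[head] - c$volume$voxels[head])), 0)
})

test_that("tissue bands respect CT physiology before noise", {
  g <- generate_control(spec0, 21)
  v <- g$volume$voxels
  expect_setequal(unique(as.numeric(v)), c(-1000, 8, 35, 40, 1000))
  # brain interior excluding ventricles is white/gray only
  soft <- v > 0 & v < 300
  expect_true(all(v[soft] %in% c(8, 35, 40)))
  brain <- v %in% c(35, 40)
  expect_true(all(v[brain] >= 3 & v[brain] <= 40))
  expect_true(any(v == 35) && any(v == 40))
})

test_that("recorded subject deformation maps landmarks back to their canonical positions", {
  for (seed in c(1, 9, 33)) {
    g <- generate_control(spec0, seed)
    centre <- g$volume$origin + (dim(g$volume$voxels) - 1) *
      g$volume$spacing / 2
    can <- ctavg:::subject_to_canonical(g$deformation, g$landmarks)
    canon <- sweep(ctavg:::phantom_canonical_landmarks(spec0), 2, centre,
                   "+")
    expect_lt(max(abs(can - canon)), 1e-6)
  }
})

test_that("lesion painting is exact: requested count, HU ceiling, bounded support", {
  les <- generate_tbi(spec0, 12, seed = 31)
  expect_equal(nrow(les$truth), 12)
  expect_true(all(les$truth$diameter_mm >= 3 & les$truth$diameter_mm <= 10))
  expect_true(all(les$truth$hu >= 60 & les$truth$hu <= 80))

  # one fixed lesion, noise off: max inside the sphere equals the lesion HU
  # and voxels beyond the 1 mm feather are untouched
  base <- generate_control(spec0, 32)$volume
  centre_vox <- round(dim(base$voxels) / 2)
  ctr <- (centre_vox - 1) * base$spacing
  one <- generate_tbi(spec0, list(lesion_spec(center = ctr,
                                              diameter_mm = 6, hu = 70)),
                      seed = 32)
  d <- dim(base$voxels)
  gcoord <- ctavg:::grid_coords(spec0)
  dist <- sqrt((gcoord$Z - ctr[1])^2 + (gcoord$Y - ctr[2])^2 +
                 (gcoord$X - ctr[3])^2)
  inside <- dist <= 3
  outside <- dist > 3 + 1
  expect_equal(max(one$volume$voxels[inside]), 70)
  expect_identical(one$volume$voxels[outside], base$voxels[outside])
})

test_that("an empty lesion list reproduces the control exactly", {
  spec_n <- phantom_spec(shape = c(36, 52, 48), spacing = c(2, 2, 2),
                         skull_semi = c(26, 40, 34), skull_thick = 5,
                         noise_sd = 3)
  a <- generate_control(spec_n, 77)
  b <- generate_tbi(spec_n, list(), seed = 77)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_equal(nrow(b$truth), 0)
})

test_that("skull collisions are rejected unless the near-bone flag is set", {
  spec_nj <- phantom_spec(shape = c(36, 52, 48), spacing = c(2, 2, 2),
                          skull_semi = c(26, 40, 34), skull_thick = 5,
                          noise_sd = 0, jitter_scale = 0,
                          jitter_rot_deg = 0, jitter_trans_mm = 0,
                          warp_amp_mm = 0.3)
  centre <- (spec_nj$shape - 1) * spec_nj$spacing / 2
  # a centre just below the skull vertex, with a radius larger than its depth
  shallow <- centre + c(spec_nj$skull_semi[1] - spec_nj$skull_thick - 2,
                        0, 0)
  expect_error(generate_tbi(spec_nj,
                            list(lesion_spec(center = shallow,
                                             diameter_mm = 8, hu = 70)),
                            seed = 40), "near_bone")
  ok <- generate_tbi(spec_nj,
                     list(lesion_spec(center = shallow, diameter_mm = 8,
                                      hu = 70, near_bone = TRUE)),
                     seed = 40)
  expect_equal(nrow(ok$truth), 1)
})

test_that("cohort generation writes the requested files and is byte-reproducible", {
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  r1 <- generate_cohort(d1, n_controls = 2, tbi_plan = c(3, 1),
                        master_seed = 9, spec = spec0)
  r2 <- generate_cohort(d2, n_controls = 2, tbi_plan = c(3, 1),
                        master_seed = 9, spec = spec0)
  expect_length(r1$controls, 2)
  expect_length(r1$tbi, 2)
  expect_equal(nrow(r1$truth), 4)
  expect_identical(readLines(r1$truth_file), readLines(r2$truth_file))
  expect_identical(readBin(r1$controls[1], "raw", 1e6),
                   readBin(r2$controls[1], "raw", 1e6))
})
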