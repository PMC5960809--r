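make_diff <- function(subject, template) subtract_template(subject, template)

test_that("subtraction is exact: self-zero, antisymmetry, grid checks", {
  set.seed(1)
  a <- volume_hu(array(rnorm(10^3, 30, 5), c(10, 10, 10)), c(2, 2, 2))
  b <- volume_hu(array(rnorm(10^3, 32, 5), c(10, 10, 10)), c(2, 2, 2))
  expect_true(all(subtract_template(a, a)$values == 0))
  d1 <- subtract_template(a, b)
  d2 <- subtract_template(b, a)
  expect_identical(d1$values, -d2$values)
  c2 <- volume_hu(a$voxels, c(1, 1, 1))
  expect_error(subtract_template(a, c2), "congruent")
})

# a synthetic detection scene with known lesions, no registration involved
lesion_scene <- function(lesions, noise = 0) {
  spec <- phantom_spec(shape = c(36, 48, 48), spacing = c(2, 2, 2),
                       skull_semi = c(26, 36, 32), skull_thick = 5,
                       noise_sd = noise, jitter_scale = 0,
                       jitter_rot_deg = 0, jitter_trans_mm = 0,
                       warp_amp_mm = 1e-6)
  clean <- generate_control(spec, 5)$volume
  les <- generate_tbi(spec, lesions, seed = 5)
  list(subject = les$volume, template = clean, truth = les$truth,
       mask = les$volume$voxels > -500)
}

test_that("a single inserted lesion yields exactly one accurate candidate", {
  ctr <- c(35, 47, 57)  # deep white matter, off the grid axes
  sc <- lesion_scene(list(lesion_spec(center = ctr, diameter_mm = 6,
                                      hu = 70)))
  dm <- make_diff(sc$subject, sc$template)
  cand <- extract_candidates(dm, sc$subject, sc$mask)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt(sum((c(cand$z, cand$y, cand$x) - ctr)^2)), 2)
  expect_lt(abs(cand$diameter_mm - 6), 2)
  expect_gte(cand$mean_hu, 60)
})

test_that("empty and sub-threshold maps yield no candidates; small lesions are size-filtered", {
  sc <- lesion_scene(list())
  dm <- make_diff(sc$subject, sc$template)
  expect_equal(nrow(extract_candidates(dm, sc$subject, sc$mask)), 0)

  # a 1 mm lesion against a 2 mm minimum diameter is discarded
  sc2 <- lesion_scene(list(lesion_spec(center = c(35, 47, 57),
                                       diameter_mm = 3.2, hu = 80)))
  dm2 <- make_diff(sc2$subject, sc2$template)
  cfg <- detection_config(min_diameter_mm = 6)
  expect_equal(nrow(extract_candidates(dm2, sc2$subject, sc2$mask, cfg)), 0)
})

test_that("raising the difference threshold never increases the candidate count", {
  set.seed(9)
  lesions <- lapply(1:4, function(i) lesion_spec())
  sc <- lesion_scene(lesions, noise = 3)
  dm <- make_diff(sc$subject, sc$template)
  counts <- vapply(c(10, 20, 25, 30, 40, 60), function(th)
    nrow(extract_candidates(dm, sc$subject, sc$mask,
                            detection_config(diff_threshold = th))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("candidates come out in a deterministic order", {
  sc <- lesion_scene(list(
    lesion_spec(center = c(35, 47, 57), diameter_mm = 7, hu = 78),
    lesion_spec(center = c(35, 33, 37), diameter_mm = 5, hu = 66)))
  dm <- make_diff(sc$subject, sc$template)
  cand <- extract_candidates(dm, sc$subject, sc$mask)
  expect_equal(nrow(cand), 2)
  expect_true(all(diff(cand$peak_diff) <= 0))
  expect_equal(cand$id, seq_len(nrow(cand)))
})

test_that("skull-adjacent hyperdensities are suppressed by the dilated bone mask", {
  sc <- lesion_scene(list())
  d <- dim(sc$subject$voxels)
  vox <- sc$subject$voxels
  # paint a bright artifact ring just inside the skull: pick voxels
  # 26-adjacent to bone
  skull <- vox > 300
  dim(skull) <- d
  rim <- ctavg:::cpp_dilate(skull, c(1, 1, 1)) & !skull & vox > -200
  vox[rim] <- 90
  subj <- volume_hu(vox, sc$subject$spacing, sc$subject$origin)
  dm <- make_diff(subj, sc$template)
  cand <- extract_candidates(dm, subj, subj$voxels > -500)
  expect_equal(nrow(cand), 0)
})

test_that("overlays encode the LUT contract and cover every slice", {
  sc <- lesion_scene(list(lesion_spec(center = c(35, 47, 57),
                                      diameter_mm = 8, hu = 80)))
  dmz <- subtract_template(sc$subject, sc$subject)   # zero map
  od <- file.path(tempdir(), "ovl_zero")
  unlink(od, recursive = TRUE)
  paths <- render_overlay(sc$subject, dmz, od)
  expect_length(paths, dim(sc$subject$voxels)[1])
  img <- png::readPNG(paths[18])
  body <- img[, seq_len(dim(sc$subject$voxels)[3]), ]
  expect_true(all(body[, , 3] >= body[, , 1] - 1e-6))  # blue band
  expect_true(all(body[, , 3] >= body[, , 2] - 1e-6))

  dm <- make_diff(sc$subject, sc$template)
  od2 <- file.path(tempdir(), "ovl_les")
  unlink(od2, recursive = TRUE)
  p2 <- render_overlay(sc$subject, dm, od2)
  sl <- round(35 / 2) + 1  # slice containing the lesion centre
  img2 <- png::readPNG(p2[sl])
  body2 <- img2[, seq_len(dim(sc$subject$voxels)[3]), ]
  yellow <- body2[, , 1] > 0.2 & body2[, , 2] > 0.2 & body2[, , 3] < 0.05
  expect_gt(sum(yellow), 0)
  # and the yellow pixels sit at the lesion's in-plane location
  yw <- which(yellow, arr.ind = TRUE)
  cen <- colMeans(yw)
  expect_lt(abs(cen[1] - (47 / 2 + 1)), 3)
  expect_lt(abs(cen[2] - (57 / 2 + 1)), 3)
})

test_that("candidate tables round trip through TSV", {
  sc <- lesion_scene(list(lesion_spec(center = c(35, 47, 57),
                                      diameter_mm = 6, hu = 72)))
  dm <- make_diff(sc$subject, sc$template)
  cand <- extract_candidates(dm, sc$subject, sc$mask)
  tf <- tempfile(fileext = ".tsv")
  write_candidates(cand, tf)
  back <- read_candidates(tf)
  expect_equal(back$x, cand$x, tolerance = 1e-6)
  expect_equal(back$voxels, cand$voxels)
})
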