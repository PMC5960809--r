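# scale space, sampler, interpolation and the mutual-information metric

test_that("the Gaussian scale space preserves constants and orders variances", {
  cst <- volume_hu(array(12, c(10, 10, 10)), c(1, 1, 1))
  pyr <- build_pyramid(cst)
  expect_length(pyr, 4)
  for (lev in pyr) expect_lt(max(abs(lev$voxels - 12)), 1e-9)

  set.seed(2)
  v <- volume_hu(array(rnorm(18^3, 0, 30), c(18, 18, 18)), c(1, 1, 1))
  pyr <- build_pyramid(v)  # sigma 4, 2, 1, 0.5
  vars <- vapply(pyr, function(p) var(as.numeric(p$voxels)), numeric(1))
  expect_true(all(diff(vars) > 0))  # less smoothing => more variance
})

test_that("smoothing a single bright voxel reproduces the sampled Gaussian kernel", {
  n <- 33
  vox <- array(0, c(n, n, n))
  vox[17, 17, 17] <- 1
  v <- volume_hu(vox, c(1, 1, 1))
  for (sigma in c(2, 1)) {
    sm <- build_pyramid(v, pyramid_config(1, sigma))[[1]]
    idx <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
    k1 <- function(t) {
      r <- max(1, ceiling(3.5 * sigma))
      w <- exp(-0.5 * ((-r):r / sigma)^2)
      (w / sum(w))[t + r + 1]
    }
    expected <- k1(idx[, 1]) * k1(idx[, 2]) * k1(idx[, 3])
    got <- sm$voxels[cbind(17 + idx[, 1], 17 + idx[, 2], 17 + idx[, 3])]
    expect_lt(max(abs(got - expected)) / max(expected), 1e-3)
  }
})

test_that("the random coordinate sampler respects the mask domain", {
  v <- volume_hu(array(0, c(10, 12, 14)), c(2, 1, 1), origin = c(5, 0, 0))
  set.seed(1)
  pts <- sample_coordinates(v, NULL, 3000)
  expect_equal(nrow(pts), 3000)
  ext <- volume_extent(v)
  expect_true(all(pts >= rep(ext["lo", ] - 1, each = 3000) &
                    pts <= rep(ext["hi", ] + 1, each = 3000)))
  # single-voxel mask: every point within that voxel's physical extent
  m <- array(FALSE, dim(v$voxels))
  m[4, 5, 6] <- TRUE
  pts1 <- sample_coordinates(v, m, 200)
  centre <- v$origin + (c(4, 5, 6) - 1) * v$spacing
  expect_true(all(abs(sweep(pts1, 2, centre)) <=
                    rep(v$spacing / 2 + 1e-9, each = 200)))
})

test_that("a moving image displaced outside the fixed domain aborts the stage", {
  spec <- phantom_spec(shape = c(24, 28, 28), spacing = c(2, 2, 2),
                       skull_semi = c(16, 20, 18), skull_thick = 4,
                       noise_sd = 0)
  f <- generate_control(spec, 1)$volume
  far <- volume_hu(f$voxels, f$spacing, f$origin + c(0, 5000, 0))
  st <- rigid_stage(center = ctavg:::com_phys(f))
  expect_error(
    asgd_optimize(st, f, far, f$voxels > -500, n_iter = 5),
    "insufficient coordinate alignments")
})

test_that("interpolation reproduces voxel values, linear ramps, and a naive cubic oracle", {
  set.seed(4)
  v <- volume_hu(array(rnorm(10 * 11 * 12, 50, 10), c(10, 11, 12)),
                 c(1.2, 1, 0.9), origin = c(2, -1, 0))
  idx <- cbind(sample(10, 30, TRUE), sample(11, 30, TRUE),
               sample(12, 30, TRUE))
  pts <- sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
  vals <- v$voxels[idx]
  expect_lt(max(abs(interpolate_volume(v, pts, 1) - vals)), 1e-6)
  expect_lt(max(abs(interpolate_volume(v, pts, 3) - vals)), 1e-6)

  # trilinear reproduces a linear ramp exactly at interior points
  ramp <- volume_hu(array(rep(1:10, 11 * 12), c(10, 11, 12)), c(1, 1, 1))
  set.seed(5)
  p <- cbind(runif(50, 0.1, 8.9), runif(50, 0.1, 9.9), runif(50, 0.1, 10.9))
  expect_lt(max(abs(interpolate_volume(ramp, p, 1) - (1 + p[, 1]))), 1e-9)

  # cubic against a naive separable B-spline sum on prefiltered coefficients
  b3 <- function(s) {
    s <- abs(s)
    ifelse(s >= 2, 0, ifelse(s >= 1, (2 - s)^3 / 6, 2 / 3 - s^2 + s^3 / 2))
  }
  coef <- ctavg:::cpp_bspline_prefilter(v$voxels)
  naive <- function(pt) {
    u <- (pt - v$origin) / v$spacing
    s <- 0
    for (i in 0:9) for (j in 0:10) for (k in 0:11)
      s <- s + coef[i + 1, j + 1, k + 1] *
        b3(u[1] - i) * b3(u[2] - j) * b3(u[3] - k)
    s
  }
  set.seed(6)
  # keep full 4x4x4 cubic support away from the mirrored border, which the
  # naive oracle does not model
  p3 <- cbind(runif(20, 4.5, 9), runif(20, 1.5, 7), runif(20, 2, 7))
  got <- interpolate_volume(v, p3, 3)
  want <- apply(p3, 1, naive)
  expect_lt(max(abs(got - want)), 1e-5)

  # outside the domain: NA marker, no exception
  expect_true(is.na(interpolate_volume(v, rbind(c(-50, 0, 0)), 1)))
})

test_that("Parzen MI matches an independent naive implementation and is symmetric", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 400
    f <- rnorm(n, 40, 12)
    m <- 0.7 * f + rnorm(n, 0, 6)
    mi <- mutual_information(f, m)
    oracle <- naive_parzen_mi(f, m)
    expect_lt(abs(mi - oracle) / max(oracle, 1e-9), 0.02)
    expect_lt(abs(mutual_information(f, m) - mutual_information(m, f)),
              1e-12)
    expect_gte(mi, -1e-9)
  }
})

test_that("the self-information identity and degenerate channels behave as defined", {
  set.seed(8)
  x <- rnorm(1000, 50, 15)
  # MI(X,X) = H(X) exactly under the matched histogram estimator
  expect_equal(mutual_information(x, x, window = "histogram"),
               sample_entropy(x, window = "histogram"), tolerance = 1e-12)
  # with the Parzen estimator, MI(X,X) is still the maximum over pairings
  scr <- mutual_information(x, sample(x))
  expect_gt(mutual_information(x, x), scr)
  # degenerate channel: MI defined as 0
  expect_identical(mutual_information(rep(3, 100), rnorm(100)), 0)
  expect_identical(mutual_information(rnorm(100), rep(2, 100)), 0)
})

test_that("independent samples give near-zero Parzen MI (3000 draws, 10 seeds)", {
  for (s in 1:10) {
    set.seed(s)
    mi <- mutual_information(runif(3000), runif(3000))
    expect_lt(mi, 0.05)
  }
})
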