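test_that("the empty chain is the identity map", {
  ch <- transform_chain(list())
  pts <- matrix(rnorm(30, 50, 20), 10, 3)
  expect_equal(chain_apply(ch, pts), pts, ignore_attr = TRUE)
})

test_that("rigid stages are isometries and affine stages preserve collinearity", {
  set.seed(1)
  for (rep in 1:20) {
    st <- rigid_stage(runif(3, -0.3, 0.3), runif(3, -10, 10),
                      runif(3, 0, 50))
    ch <- transform_chain(st)
    a <- matrix(runif(9, -40, 40), 3, 3)
    b <- chain_apply(ch, a)
    da <- dist(a)
    db <- dist(b)
    expect_lt(max(abs(da - db) / pmax(da, 1e-12)), 1e-9)
  }
  for (rep in 1:20) {
    M <- diag(3) + matrix(runif(9, -0.2, 0.2), 3, 3)
    ch <- transform_chain(affine_stage(M, runif(3, -5, 5), runif(3, 0, 40)))
    p0 <- runif(3, -20, 20)
    dirn <- runif(3, -1, 1)
    lam <- c(0, 0.35, 1)
    tri <- t(vapply(lam, function(l) p0 + l * dirn, numeric(3)))
    out <- chain_apply(ch, tri)
    # mapped middle point still lies on the segment at the same ratio
    expect_lt(max(abs(out[2, ] - (out[1, ] + 0.35 * (out[3, ] - out[1, ])))),
              1e-9)
  }
})

test_that("zero B-spline coefficients give the identity; constant coefficients prove partition of unity", {
  g <- list(origin = c(-20, -20, -20), spacing = c(20, 20, 20),
            dim = c(8L, 9L, 9L))
  zero <- bspline_stage(g$origin, g$spacing, g$dim)
  set.seed(2)
  pts <- cbind(runif(1000, 10, 80), runif(1000, 10, 90),
               runif(1000, 10, 90))
  out <- chain_apply(transform_chain(zero), pts)
  expect_lt(max(abs(out - pts)), 1e-12)

  # displacement under constant coefficients equals that constant at every
  # point iff the cubic basis functions sum to one there
  cf <- array(0, c(g$dim, 3))
  cf[, , , 1] <- 2.5
  cf[, , , 2] <- -1.25
  cf[, , , 3] <- 0.5
  cst <- bspline_stage(g$origin, g$spacing, g$dim, cf)
  out2 <- chain_apply(transform_chain(cst), pts)
  disp <- out2 - pts
  expect_lt(max(abs(sweep(disp, 2, c(2.5, -1.25, 0.5)))), 1e-9)
})

test_that("stages compose sequentially and the chain survives serialization", {
  st1 <- rigid_stage(c(0.1, -0.05, 0.2), c(3, -2, 1), c(10, 20, 30))
  st2 <- affine_stage(diag(c(1.05, 0.95, 1.02)), c(-1, 0.5, 2),
                      c(10, 20, 30))
  g <- list(origin = c(-30, -30, -30), spacing = c(25, 25, 25),
            dim = c(6L, 6L, 6L))
  set.seed(3)
  st3 <- bspline_stage(g$origin, g$spacing, g$dim,
                       array(rnorm(prod(g$dim) * 3, 0, 0.5), c(g$dim, 3)))
  ch <- transform_chain(st1, st2, st3)
  pts <- matrix(runif(60, 0, 60), 20, 3)
  # manual sequential application: affine(rigid(x)) + u(x)
  y1 <- chain_apply(transform_chain(st1), pts)
  y2 <- chain_apply(transform_chain(st2), y1)
  u <- chain_apply(transform_chain(st3), pts) - pts
  expect_equal(chain_apply(ch, pts), y2 + u, tolerance = 1e-12)

  tf <- tempfile(fileext = ".txt")
  write_chain(ch, tf)
  ch2 <- read_chain(tf)
  expect_equal(chain_apply(ch2, pts), chain_apply(ch, pts),
               tolerance = 1e-12)
})

test_that("resampling honours identity, pure shifts and the fill contract", {
  set.seed(4)
  v <- volume_hu(array(rnorm(12^3, 30, 10), c(12, 12, 12)), c(1, 1, 1))
  idchain <- transform_chain(list())
  r <- resample_volume(v, idchain, v, order = 3)
  expect_lt(max(abs(r$voxels - v$voxels)), 1e-5)

  # translating the sampling by exactly one voxel along rows shifts the
  # array by one voxel; the vacated border is filled with air
  sh <- resample_volume(v, transform_chain(
    rigid_stage(trans = c(0, 1, 0))), v, order = 1)
  expect_equal(sh$voxels[, 1:11, ], v$voxels[, 2:12, ], tolerance = 1e-9)
  expect_true(all(sh$voxels[, 12, ] == -1000))

  far <- resample_volume(v, transform_chain(
    rigid_stage(trans = c(0, 1e5, 0))), v)
  expect_true(all(far$voxels == -1000))
})
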