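# registration-level properties; parameter-recovery accuracy is exercised
# at full budget in test-acceptance.R

test_that("metric gradients vanish at the optimum and point toward alignment", {
  f <- cached("reg_fixed", generate_control(small_spec(), 7)$volume)
  set.seed(11)
  pts <- sample_coordinates(f, f$voxels > -200, 3000)
  centre <- ctavg:::com_phys(f)
  rng <- c(-1100, 1100, -1100, 1100)

  # identical images, all-zero B-spline: near-stationary, and a coherent
  # 3 mm whole-field offset produces a distinctly larger pull directed back
  # toward the optimum
  g <- ctavg:::default_bspline_grid(f, 20)
  zero <- bspline_stage(g$origin, g$spacing, g$dim)
  at_opt <- metric_gradient(f, f, pts, zero, order = 1, range = rng)
  cf <- array(0, c(g$dim, 3))
  cf[, , , 2] <- 3
  off <- bspline_stage(g$origin, g$spacing, g$dim, cf)
  off_opt <- metric_gradient(f, f, pts, off, order = 1, range = rng)
  expect_lt(sqrt(sum(at_opt$grad^2)), 0.75 * sqrt(sum(off_opt$grad^2)))
  # cost increases along the offset direction: its gradient projects
  # positively on the displacement
  expect_gt(sum(off_opt$grad * as.numeric(cf)), 0)

  # displaced pair: the translation gradient of the cost must point to
  # reduce the displacement in nearly all trials
  hits <- 0
  for (trial in 1:20) {
    set.seed(100 + trial)
    tr <- runif(3, -4, 4)
    moving <- resample_volume(f, transform_chain(
      rigid_stage(trans = -tr)), f, order = 1)
    st <- rigid_stage(center = centre)  # chain must move by +tr
    pts_t <- sample_coordinates(f, f$voxels > -200, 600)
    res <- metric_gradient(f, moving, pts_t, st, order = 1, range = rng)
    step <- -res$grad[4:6]  # descent direction on the translations
    if (sum(step * tr) > 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("registration is deterministic given a seed", {
  f <- cached("reg_fixed", generate_control(small_spec(), 7)$volume)
  m <- cached("reg_moving", generate_control(small_spec(), 8)$volume)
  ch1 <- register(f, m, opt = quick_opt(), seed = 5)
  ch2 <- register(f, m, opt = quick_opt(), seed = 5)
  expect_identical(ch1, ch2)
  ch3 <- register(f, m, opt = quick_opt(), seed = 6)
  expect_false(identical(ch1, ch3))
})

test_that("self-registration returns a near-identity chain", {
  f <- cached("reg_fixed", generate_control(small_spec(), 7)$volume)
  ch <- register(f, f, seed = 3)
  hp <- mask_points(f, f$voxels > -200, 3000, seed = 2)
  disp <- sqrt(rowSums((chain_apply(ch, hp) - hp)^2))
  expect_lt(mean(disp), 0.5)
})

test_that("registering two different subjects increases the head-voxel correlation", {
  f <- cached("reg_fixed", generate_control(small_spec(), 7)$volume)
  m <- cached("reg_moving", generate_control(small_spec(), 8)$volume)
  ch <- register(f, m, seed = 5)
  reg <- resample_volume(m, ch, f)
  head <- f$voxels > -200
  before <- cor(f$voxels[head], m$voxels[head])
  after <- cor(f$voxels[head], reg$voxels[head])
  expect_gt(after, before)
  expect_gt(after, 0.7)
})

test_that("stage failures carry the stage name", {
  f <- cached("reg_fixed", generate_control(small_spec(), 7)$volume)
  # a moving volume so small that almost no sampled fixed-head points can
  # land inside it, whatever the initial alignment
  tiny <- volume_hu(array(50, c(3, 3, 3)), c(2, 2, 2))
  expect_error(register(f, tiny, stages = "rigid", opt = quick_opt(),
                        seed = 1),
               "stage 'rigid'.*insufficient coordinate alignments")
})
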