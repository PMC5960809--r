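# Shared fixtures. Heavy artifacts are built lazily and cached for the
# whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a head phantom fully contained in a small grid (for registration tests)
small_spec <- function(...) {
  phantom_spec(shape = c(48, 56, 56), spacing = c(2, 2, 2),
               skull_semi = c(34, 44, 38), skull_thick = 6, ...)
}

# reduced-budget optimizer for tests of properties that do not depend on
# the iteration budget
quick_opt <- function() optimizer_config(rigid_iters = 120,
                                         affine_iters = 120,
                                         bspline_iters = 200)

# physical points of a random subset of voxels in a mask
mask_points <- function(vol, mask, n, seed = 1) {
  set.seed(seed)
  idx <- which(mask)
  idx <- sample(idx, min(n, length(idx)))
  ai <- arrayInd(idx, dim(vol$voxels))
  sweep(sweep(ai - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# independent naive R implementation of the Parzen-window MI estimator
# (H_F + H_M - H_J from an explicitly assembled joint histogram)
naive_parzen_mi <- function(f, m, nbins = 32) {
  b3 <- function(s) {
    s <- abs(s)
    ifelse(s >= 2, 0, ifelse(s >= 1, (2 - s)^3 / 6, 2 / 3 - s^2 + s^3 / 2))
  }
  if (diff(range(f)) < 1e-12 || diff(range(m)) < 1e-12) return(0)
  to_bin <- function(x) pmin(1 + (x - min(x)) * (nbins - 4) / diff(range(x)),
                             nbins - 3 - 1e-9)
  uf <- to_bin(f)
  um <- to_bin(m)
  H <- matrix(0, nbins, nbins)
  for (i in seq_along(uf)) {
    for (a in 0:(nbins - 1)) {
      wa <- b3(uf[i] - a)
      if (wa == 0) next
      for (b in 0:(nbins - 1)) {
        wb <- b3(um[i] - b)
        if (wb > 0) H[a + 1, b + 1] <- H[a + 1, b + 1] + wa * wb
      }
    }
  }
  p <- H / length(uf)
  pf <- rowSums(p)
  pm <- colSums(p)
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  ent(pf) + ent(pm) - ent(p)
}

# build a moving image that is `vol` observed under the given true chain
# (fixed -> moving), by resampling through the chain's inverse
apply_known_affine <- function(vol, M, tr, centre) {
  Minv <- solve(M)
  inv <- transform_chain(affine_stage(Minv, -as.numeric(Minv %*% tr),
                                      centre))
  resample_volume(vol, inv, vol, order = 3)
}

# smooth random displacement field over the volume, rescaled so the maximum
# in-head displacement equals `amp_mm`; returns the deformation object plus
# the warped volume (moving(y) = vol(Tinv(y)) with T(x) = x + d(x))
apply_known_warp <- function(vol, spec, amp_mm = 3, seed = 5) {
  centre <- vol$origin + (dim(vol$voxels) - 1) * vol$spacing / 2
  set.seed(seed)
  def <- ctavg:::draw_subject_deformation(spec, centre, volume_extent(vol))
  d <- dim(vol$voxels)
  gcoord <- ctavg:::grid_coords(spec)
  pts <- cbind(gcoord$Z, gcoord$Y, gcoord$X)
  head <- as.numeric(vol$voxels) > -200
  dn <- sqrt(rowSums(ctavg:::warp_eval(def, pts[head, ])^2))
  def$warp$comp <- lapply(def$warp$comp, function(a) a * amp_mm / max(dn))
  x <- pts
  for (i in 1:60) x <- pts - ctavg:::warp_eval(def, x)
  vals <- interpolate_volume(vol, x, order = 3)
  vals[is.na(vals)] <- -1000
  list(def = def,
       moving = volume_hu(array(vals, d), vol$spacing, vol$origin),
       forward = function(p) p + ctavg:::warp_eval(def, p))
}

# ---- heavy shared fixtures (acceptance scale) ----------------------------

# the default synthetic cohort pipeline at half resolution
acceptance_run <- function() {
  cached("acceptance_run", {
    out <- file.path(tempdir(), "ctavg_acceptance")
    run_pipeline(list(seed = 42, out_dir = out, fast = TRUE))
  })
}

# stack 3-D arrays along the axial (first) axis
abind_slices <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                    d[2], d[3]))
  at <- 1
  for (p in parts) {
    out[at:(at + dim(p)[1] - 1), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
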