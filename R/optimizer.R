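#' Adaptive stochastic gradient descent for one transform stage
#'
#' Minimises the negated mutual information over the active stage's
#' parameters with step size \code{a / (A + t_k)^alpha}. The adaptive time
#' t_k is advanced by a sigmoid of the (normalised, negated) inner product
#' of successive stochastic gradients: correlated gradients shrink t (larger
#' steps), anti-correlated ones grow it. Every iteration draws a fresh set
#' of random coordinates; an iteration with fewer than
#' \code{sampler$min_valid} valid alignments aborts the stage. Fully
#' deterministic given the R random seed.
#'
#' Rotation and affine-matrix parameters are internally scaled by the
#' sampling-region radius so one internal unit moves a peripheral point by
#' roughly 1 mm; the gain \code{a} is calibrated from the first stochastic
#' gradient so the initial step length is about \code{delta} mm, and the
#' returned parameters average the final iterates to damp the stochastic
#' tail.
#'
#' @param stage a \code{ctavg_stage} holding the initial parameters.
#' @param fixed,moving single-level (already smoothed) \code{ctavg_volume}s;
#'   for \code{order = 3} both must already be B-spline prefiltered.
#' @param fixed_mask logical array over \code{fixed}: the sampling domain.
#' @param order interpolation order for this level (1 or 3).
#' @param n_iter iteration budget for this call.
#' @param pre_chain frozen global chain applied before a rigid/affine stage
#'   (the stage then optimises the residual).
#' @param global_chain frozen global chain preceding a B-spline stage.
#' @param sampler,metric,opt configuration objects.
#' @param delta target first-step length (mm); default one mean voxel.
#' @return the optimized \code{ctavg_stage}.
#' @export
asgd_optimize <- function(stage, fixed, moving, fixed_mask,
                          order = 1, n_iter = 500,
                          pre_chain = NULL, global_chain = NULL,
                          sampler = sampler_config(),
                          metric = metric_config(),
                          opt = optimizer_config(),
                          delta = NULL) {
  stopifnot_volume(fixed)
  stopifnot_volume(moving)
  bb <- mask_bbox(fixed, fixed_mask)
  if (is.null(delta)) delta <- mean(fixed$spacing)
  radius <- max(sqrt(sum(((bb$hi - bb$lo) / 2)^2)) / sqrt(3), 1)

  pre <- if (is.null(pre_chain)) NULL else chain_parts(pre_chain)
  gl <- NULL
  bs <- NULL
  if (stage$kind == "rigid") {
    params <- c(stage$angles, stage$trans)
    scales <- c(rep(radius, 3), rep(1, 3))
    center <- stage$center
  } else if (stage$kind == "affine") {
    params <- c(as.numeric(t(stage$M)), stage$trans)
    scales <- c(rep(radius, 9), rep(1, 3))
    center <- stage$center
  } else if (stage$kind == "bspline") {
    params <- as.numeric(stage$coef)
    scales <- rep(1, length(params))
    center <- c(0, 0, 0)
    gl <- if (is.null(global_chain)) NULL else chain_parts(global_chain)
    bs <- list(origin = stage$origin, spacing = stage$spacing,
               dim = stage$dim, coef = stage$coef)
  } else stop("unknown stage kind: ", stage$kind)

  # freeze the intensity-to-bin mapping for this stage: min/max of the
  # intensities sampled under the initial transform, padded slightly
  rng_pts <- cpp_sample_mask_points(fixed_mask, fixed$spacing,
                                    fixed$origin, bb$lo, bb$hi,
                                    sampler$n_samples)
  init_chain <- if (stage$kind == "bspline")
    transform_chain(c(if (is.null(global_chain)) list()
                      else global_chain$stages, list(stage)))
  else
    transform_chain(c(if (is.null(pre_chain)) list()
                      else pre_chain$stages, list(stage)))
  fvals <- cpp_eval_points(fixed$voxels, fixed$spacing, fixed$origin,
                           as.integer(order), rng_pts)
  mvals <- cpp_eval_points(moving$voxels, moving$spacing, moving$origin,
                           as.integer(order),
                           chain_apply(init_chain, rng_pts))
  ok <- is.finite(fvals) & is.finite(mvals)
  if (sum(ok) < sampler$min_valid)
    insufficient_alignment(sum(ok), sampler$min_valid, stage$kind)
  fvals <- fvals[ok]
  mvals <- mvals[ok]
  pad <- function(r) r + c(-1, 1) * 0.05 * max(diff(r), 1e-9)
  frange <- pad(range(fvals, na.rm = TRUE))
  mrange <- pad(range(mvals, na.rm = TRUE))
  stage_range <- c(frange, mrange)

  q <- params * scales  # internal (scaled) parameters
  tk <- 0
  a_gain <- NULL
  g_prev <- NULL
  n_avg <- max(1L, ceiling(opt$avg_frac * n_iter))
  q_avg <- numeric(length(q))
  navg_seen <- 0L

  for (k in seq_len(n_iter)) {
    pts <- cpp_sample_mask_points(fixed_mask, fixed$spacing, fixed$origin,
                                  bb$lo, bb$hi, sampler$n_samples)
    params <- q / scales
    if (stage$kind == "bspline") {
      bs$coef <- array(params, c(stage$dim, 3L))
      res <- mi_grad_stage(fixed, order, moving, order, pts, "bspline",
                           numeric(0), center, global_ = gl, bs = bs,
                           n_bins = metric$n_bins, want_grad = TRUE,
                           range = stage_range)
    } else {
      res <- mi_grad_stage(fixed, order, moving, order, pts, stage$kind,
                           params, center, pre = pre,
                           n_bins = metric$n_bins, want_grad = TRUE,
                           range = stage_range)
    }
    if (res$n_valid < sampler$min_valid)
      insufficient_alignment(res$n_valid, sampler$min_valid, stage$kind)
    g <- -res$grad / scales  # gradient of the cost (-MI) in scaled space
    gn <- sqrt(sum(g * g))
    if (is.null(a_gain)) {
      # calibrate the gain from the median norm of a few probe gradients so
      # a single unlucky draw cannot set an oversized step
      probe <- gn
      n_probe <- min(4L, max(0L, n_iter - k))
      for (p in seq_len(n_probe)) {
        pp <- cpp_sample_mask_points(fixed_mask, fixed$spacing,
                                     fixed$origin, bb$lo, bb$hi,
                                     sampler$n_samples)
        rp <- if (stage$kind == "bspline")
          mi_grad_stage(fixed, order, moving, order, pp, "bspline",
                        numeric(0), center, global_ = gl, bs = bs,
                        n_bins = metric$n_bins, want_grad = TRUE,
                        range = stage_range)
        else
          mi_grad_stage(fixed, order, moving, order, pp, stage$kind,
                        params, center, pre = pre,
                        n_bins = metric$n_bins, want_grad = TRUE,
                        range = stage_range)
        probe <- c(probe, sqrt(sum((rp$grad / scales)^2)))
      }
      a_gain <- delta * (opt$A + 1)^opt$alpha /
        max(stats::median(probe), 1e-12)
    }
    if (!is.null(g_prev)) {
      gpn <- sqrt(sum(g_prev * g_prev))
      x <- -sum(g * g_prev) / max(gn * gpn, 1e-300)
      fsig <- opt$fmin + (opt$fmax - opt$fmin) / (1 + exp(-x / opt$omega))
      tk <- max(0, tk + fsig)
    }
    gamma <- a_gain / (opt$A + tk + 1)^opt$alpha
    step <- gamma * g
    sl <- sqrt(sum(step * step))
    if (sl > 2 * delta) step <- step * (2 * delta / sl)  # trust region
    q <- q - step
    g_prev <- g
    if (k > n_iter - n_avg) {
      q_avg <- q_avg + q
      navg_seen <- navg_seen + 1L
    }
  }
  q <- q_avg / max(navg_seen, 1L)
  params <- q / scales

  if (stage$kind == "rigid") {
    rigid_stage(params[1:3], params[4:6], center)
  } else if (stage$kind == "affine") {
    affine_stage(matrix(params[1:9], 3, 3, byrow = TRUE), params[10:12],
                 center)
  } else {
    bspline_stage(stage$origin, stage$spacing, stage$dim,
                  array(params, c(stage$dim, 3L)))
  }
}

# centre of mass (mm) of voxels above a threshold
com_phys <- function(vol, hu_threshold = -200) {
  m <- vol$voxels > hu_threshold
  if (!any(m)) m <- array(TRUE, dim(vol$voxels))
  w <- which(m, arr.ind = TRUE)
  colMeans(voxel_to_phys(vol, w))
}

# default B-spline grid covering the fixed domain plus a one-spacing margin,
# padded so every domain point has full 4x4x4 cubic support
default_bspline_grid <- function(fixed, cp_spacing = 20) {
  ext <- volume_extent(fixed)
  lo <- ext["lo", ] - cp_spacing
  n <- as.integer(ceiling((ext["hi", ] + cp_spacing - lo) / cp_spacing)) + 4L
  list(origin = lo - cp_spacing, spacing = rep(cp_spacing, 3), dim = n)
}

#' Register a moving volume to a fixed volume
#'
#' Runs the multi-stage, multi-resolution registration: for each requested
#' stage (rigid, then affine, then B-spline free-form deformation) the
#' Gaussian scale space is traversed coarse to fine, with trilinear
#' interpolation on all but the final level and cubic B-spline interpolation
#' on the final one; each stage starts from the previous stage's result. The
#' rigid stage is initialised by aligning head centres of mass (absorbing
#' pose differences); the affine stage refines the residual after the rigid
#' map; the B-spline stage adds a free-form displacement, evaluated at the
#' fixed-space point, on a regular control grid.
#'
#' @param fixed,moving preprocessed \code{ctavg_volume}s.
#' @param stages character vector, subset of
#'   \code{c("rigid", "affine", "bspline")} in order.
#' @param fixed_mask logical sampling mask over \code{fixed}; default is all
#'   voxels above -500 HU (head plus skull).
#' @param pyramid,sampler,metric,opt configuration objects.
#' @param cp_spacing B-spline control-point spacing (mm; default 20).
#' @param seed optional integer seed for the stochastic sampler.
#' @param verbose print per-stage progress.
#' @return a \code{ctavg_chain} mapping fixed space to moving space.
#' @export
register <- function(fixed, moving,
                     stages = c("rigid", "affine", "bspline"),
                     fixed_mask = NULL,
                     pyramid = pyramid_config(),
                     sampler = sampler_config(),
                     metric = metric_config(),
                     opt = optimizer_config(),
                     cp_spacing = 20, seed = NULL, verbose = FALSE) {
  stopifnot_volume(fixed)
  stopifnot_volume(moving)
  stages <- match.arg(stages, c("rigid", "affine", "bspline"),
                      several.ok = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(fixed_mask)) fixed_mask <- fixed$voxels > -500

  pyr_f <- build_pyramid(fixed, pyramid)
  pyr_m <- build_pyramid(moving, pyramid)
  orders <- c(rep(1L, pyramid$levels - 1L), 3L)
  pf <- function(v) volume_hu(cpp_bspline_prefilter(v$voxels), v$spacing,
                              v$origin)
  lv_f <- lapply(seq_len(pyramid$levels), function(l)
    if (orders[l] == 3L) pf(pyr_f[[l]]) else pyr_f[[l]])
  lv_m <- lapply(seq_len(pyramid$levels), function(l)
    if (orders[l] == 3L) pf(pyr_m[[l]]) else pyr_m[[l]])

  centre <- com_phys(fixed)
  done <- list()  # completed stages, in order

  split_iters <- function(total, nlev) {
    base <- rep(total %/% nlev, nlev)
    base[nlev] <- base[nlev] + total - sum(base)
    base
  }
  global_of <- function(stages_list) transform_chain(
    Filter(function(s) s$kind != "bspline", stages_list))

  for (st in stages) {
    n_total <- switch(st, rigid = opt$rigid_iters,
                      affine = opt$affine_iters,
                      bspline = opt$bspline_iters)
    per_level <- split_iters(n_total, pyramid$levels)
    stage <- switch(st,
      rigid = rigid_stage(trans = com_phys(moving) - centre,
                          center = centre),
      affine = affine_stage(center = centre),
      bspline = {
        g <- default_bspline_grid(fixed, cp_spacing)
        bspline_stage(g$origin, g$spacing, g$dim)
      })
    pre_chain <- if (st %in% c("rigid", "affine") && length(done))
      global_of(done) else NULL
    glob_chain <- if (st == "bspline") global_of(done) else NULL
    for (lev in seq_len(pyramid$levels)) {
      delta <- mean(fixed$spacing) * 0.5^(lev - 1)
      stage <- tryCatch(
        asgd_optimize(stage, lv_f[[lev]], lv_m[[lev]], fixed_mask,
                      order = orders[lev], n_iter = per_level[lev],
                      pre_chain = pre_chain, global_chain = glob_chain,
                      sampler = sampler, metric = metric, opt = opt,
                      delta = delta),
        ctavg_alignment_error = function(e)
          stop(sprintf("registration stage '%s' failed: %s", st,
                       conditionMessage(e)), call. = FALSE))
      if (verbose) message(sprintf("  stage %s level %d done", st, lev))
    }
    done[[length(done) + 1L]] <- stage
  }
  transform_chain(done)
}
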