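#' Registration configuration objects
#'
#' Defaults reproduce the study's registration recipe: a four-level Gaussian
#' scale space (sigma 4/2/1/0.5 voxels, smoothing only, no downsampling),
#' a random coordinate sampler drawing 3000 fresh points per iteration with
#' at least 150 required valid alignments, a 32-bin mutual-information
#' metric with cubic B-spline Parzen windows, and adaptive stochastic
#' gradient descent with 1500 iterations for the rigid and affine stages and
#' 2500 for the B-spline stage (split evenly across the pyramid levels).
#'
#' @param levels number of scale-space levels.
#' @param sigmas per-level Gaussian smoothing standard deviations, in voxel
#'   units, strictly decreasing.
#' @return a config list of the corresponding class.
#' @name registration-config
NULL

#' @rdname registration-config
#' @export
pyramid_config <- function(levels = 4, sigmas = c(4, 2, 1, 0.5)) {
  if (length(sigmas) != levels) stop("levels must equal length(sigmas)")
  if (any(sigmas <= 0) || any(diff(sigmas) >= 0))
    stop("sigmas must be strictly decreasing and positive")
  structure(list(levels = as.integer(levels), sigmas = as.numeric(sigmas)),
            class = "ctavg_pyramid_config")
}

#' @rdname registration-config
#' @param n_samples random coordinates drawn per optimizer iteration.
#' @param min_valid minimum sampled points that must land inside both image
#'   domains for an iteration to count; fewer aborts the stage.
#' @export
sampler_config <- function(n_samples = 3000, min_valid = 150) {
  if (min_valid > n_samples) stop("min_valid must be <= n_samples")
  structure(list(n_samples = as.integer(n_samples),
                 min_valid = as.integer(min_valid)),
            class = "ctavg_sampler_config")
}

#' @rdname registration-config
#' @param n_bins joint-histogram bins per intensity channel (>= 2).
#' @export
metric_config <- function(n_bins = 32) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(n_bins = as.integer(n_bins)), class = "ctavg_metric_config")
}

#' @rdname registration-config
#' @param rigid_iters,affine_iters,bspline_iters per-stage iteration budgets
#'   (totals, split across pyramid levels).
#' @param alpha,A gain-decay parameters of the step size
#'   \code{a / (A + t_k)^alpha}.
#' @param fmin,fmax,omega sigmoid parameters of the adaptive time update
#'   (decrease t on correlated successive gradients, increase on
#'   anti-correlated ones).
#' @param delta0 initial step length (mm) at the coarsest level; halved at
#'   each finer level. The gain \code{a} is calibrated per level so the
#'   first step moves approximately this far.
#' @param avg_frac fraction of final iterates averaged into the returned
#'   parameter estimate (stabilises the stochastic tail).
#' @export
optimizer_config <- function(rigid_iters = 1500, affine_iters = 1500,
                             bspline_iters = 2500, alpha = 0.602, A = 20,
                             fmin = -0.8, fmax = 1, omega = 0.2,
                             delta0 = NULL, avg_frac = 0.25) {
  if (any(c(rigid_iters, affine_iters, bspline_iters) <= 0))
    stop("iteration counts must be positive")
  structure(list(rigid_iters = as.integer(rigid_iters),
                 affine_iters = as.integer(affine_iters),
                 bspline_iters = as.integer(bspline_iters),
                 alpha = alpha, A = A, fmin = fmin, fmax = fmax,
                 omega = omega, delta0 = delta0, avg_frac = avg_frac),
            class = "ctavg_optimizer_config")
}

#' Build a Gaussian scale space
#'
#' Level L is the input convolved with an isotropic Gaussian of
#' \code{sigmas[L]} voxels; the grid is unchanged (smoothing-only pyramid),
#' and the final level uses the smallest sigma.
#'
#' @param vol a \code{ctavg_volume}
#' @param cfg a [pyramid_config()]
#' @return list of \code{ctavg_volume}, coarsest first.
#' @export
build_pyramid <- function(vol, cfg = pyramid_config()) {
  stopifnot_volume(vol)
  lapply(cfg$sigmas, function(s) {
    volume_hu(cpp_gauss_smooth(vol$voxels, rep(s, 3)), vol$spacing,
              vol$origin)
  })
}

#' Draw random coordinates over a mask's physical domain
#'
#' Continuous (off-grid) points uniformly distributed over the physical
#' support of the mask; a fresh draw is taken every optimizer iteration.
#'
#' @param vol the \code{ctavg_volume} the mask lives on.
#' @param mask logical array congruent with \code{vol} (NULL = everywhere).
#' @param n number of points.
#' @return n x 3 matrix of physical points (mm).
#' @export
sample_coordinates <- function(vol, mask = NULL, n = 3000) {
  stopifnot_volume(vol)
  if (is.null(mask)) mask <- array(TRUE, dim(vol$voxels))
  if (!any(mask)) stop("empty sampling mask")
  bb <- mask_bbox(vol, mask)
  cpp_sample_mask_points(mask, vol$spacing, vol$origin, bb$lo, bb$hi,
                         as.integer(n))
}

# physical bounding box (voxel centres +- half voxel) of a mask
mask_bbox <- function(vol, mask) {
  w <- which(mask, arr.ind = TRUE)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  list(lo = vol$origin + (lo - 1 - 0.5) * vol$spacing,
       hi = vol$origin + (hi - 1 + 0.5) * vol$spacing)
}

#' Mutual information between paired intensity samples
#'
#' Computed from a joint histogram with cubic B-spline Parzen windows
#' (\code{window = "parzen"}, the differentiable estimator driving the
#' optimizer) or a plain zero-order histogram (\code{window = "histogram"}).
#' Intensities are mapped to bin space by each list's min/max; a degenerate
#' channel (max equal to min) yields 0. Result is in nats; the optimizer
#' minimises its negative.
#'
#' @param fixed_samples,moving_samples paired numeric vectors of equal
#'   length.
#' @param cfg a [metric_config()]
#' @param window \code{"parzen"} or \code{"histogram"}
#' @return scalar MI (nats)
#' @export
mutual_information <- function(fixed_samples, moving_samples,
                               cfg = metric_config(),
                               window = c("parzen", "histogram")) {
  window <- match.arg(window)
  if (length(fixed_samples) != length(moving_samples))
    stop("sample lists must have equal length")
  cpp_mi_samples(as.numeric(fixed_samples), as.numeric(moving_samples),
                 cfg$n_bins, if (window == "parzen") 3L else 0L)
}

#' Marginal Parzen-histogram entropy of an intensity sample list
#'
#' @inheritParams mutual_information
#' @param x numeric sample vector
#' @return scalar entropy (nats)
#' @export
sample_entropy <- function(x, cfg = metric_config(),
                           window = c("parzen", "histogram")) {
  window <- match.arg(window)
  cpp_entropy_samples(as.numeric(x), cfg$n_bins,
                      if (window == "parzen") 3L else 0L)
}

# ---- internal: stage representation used during optimization --------------

# Evaluate MI and its gradient for the active stage at the given sample
# points. `pre` is the frozen composed global transform applied before a
# rigid/affine stage (its output feeds the stage); for the B-spline stage
# `global_` is the frozen global part and `bs` carries the current
# coefficients.
mi_grad_stage <- function(fixed, forder, moving, morder, pts, stage_kind,
                          params, center, pre = NULL, global_ = NULL,
                          bs = NULL, n_bins = 32, want_grad = TRUE,
                          range = NULL) {
  if (is.null(global_)) global_ <- list(M = diag(3), b = c(0, 0, 0))
  if (is.null(pre)) pre <- list(M = diag(3), b = c(0, 0, 0))
  kind <- switch(stage_kind, none = 0L, rigid = 1L, affine = 2L,
                 bspline = 3L)
  cpp_mi_grad(fixed$voxels, fixed$spacing, fixed$origin, as.integer(forder),
              moving$voxels, moving$spacing, moving$origin,
              as.integer(morder), pts, pre$M, pre$b, global_$M, global_$b,
              bs, kind, as.numeric(params), as.numeric(center),
              as.integer(n_bins), want_grad,
              if (is.null(range)) numeric(0) else as.numeric(range))
}

#' Gradient of the mutual-information cost for one transform stage
#'
#' Analytic gradient of the (negated) Parzen-window mutual information with
#' respect to the active stage's parameters, chained through the moving
#' image's spatial gradient and the transform Jacobian. Agrees with central
#' finite differences; mainly exposed for verification.
#'
#' @param fixed,moving \code{ctavg_volume}s (for cubic order, prefiltered
#'   internally).
#' @param pts n x 3 sample points (fixed space, mm).
#' @param stage a \code{ctavg_stage} (rigid, affine or bspline).
#' @param global_chain optional \code{ctavg_chain} of frozen global stages
#'   preceding a bspline stage.
#' @param order interpolation order (1 or 3).
#' @param cfg a [metric_config()]
#' @param range optional frozen intensity range
#'   \code{c(fmin, fmax, mmin, mmax)}; default maps bins from the current
#'   samples' min/max.
#' @return \code{list(value, grad, n_valid)}; \code{value} is MI (nats),
#'   \code{grad} is the gradient of \code{-MI} over stage parameters.
#' @export
metric_gradient <- function(fixed, moving, pts, stage, global_chain = NULL,
                            order = 1, cfg = metric_config(),
                            range = NULL) {
  fixed_src <- if (order == 3)
    volume_hu(cpp_bspline_prefilter(fixed$voxels), fixed$spacing,
              fixed$origin) else fixed
  moving_src <- if (order == 3)
    volume_hu(cpp_bspline_prefilter(moving$voxels), moving$spacing,
              moving$origin) else moving
  gl <- NULL
  bs <- NULL
  pre <- NULL
  params <- numeric(0)
  center <- c(0, 0, 0)
  if (stage$kind == "rigid") {
    params <- c(stage$angles, stage$trans)
    center <- stage$center
    pre <- if (is.null(global_chain)) NULL else chain_parts(global_chain)
  } else if (stage$kind == "affine") {
    params <- c(as.numeric(t(stage$M)), stage$trans)
    center <- stage$center
    pre <- if (is.null(global_chain)) NULL else chain_parts(global_chain)
  } else if (stage$kind == "bspline") {
    gl <- if (is.null(global_chain)) NULL else chain_parts(global_chain)
    bs <- list(origin = stage$origin, spacing = stage$spacing,
               dim = stage$dim, coef = stage$coef)
  } else stop("unknown stage kind")
  res <- mi_grad_stage(fixed_src, order, moving_src, order, pts,
                       stage$kind, params, center, pre = pre, global_ = gl,
                       bs = bs, n_bins = cfg$n_bins, want_grad = TRUE,
                       range = range)
  res$grad <- -res$grad  # cost is -MI
  res
}

# condition raised when fewer than min_valid samples align
insufficient_alignment <- function(n_valid, min_valid, where = "") {
  stop(structure(class = c("ctavg_alignment_error", "error", "condition"),
                 list(message = sprintf(
                   "insufficient coordinate alignments%s: %d valid < %d required",
                   if (nzchar(where)) paste0(" in ", where) else "",
                   n_valid, min_valid), call = NULL)))
}
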