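#' Build the average-brain CT template
#'
#' Registers every control (including the one chosen as the fixed image) to
#' the fixed control with the full rigid/affine/B-spline chain, resamples
#' each onto the fixed grid, and takes the voxelwise arithmetic mean, so
#' each template voxel is the average of the co-registered controls at that
#' point. A control whose registration fails is dropped with a warning; the
#' build aborts if fewer than two controls survive.
#'
#' Per-control sampler seeds are derived from \code{seed} and the control's
#' position in the list, so the build is reproducible and (for a fixed
#' \code{fixed_index} identity) order-invariant.
#'
#' @param controls list of preprocessed \code{ctavg_volume}s (>= 2).
#' @param fixed_index index of the control used as the fixed image.
#' @param ids optional character identifiers for provenance.
#' @param stages,pyramid,sampler,metric,opt,cp_spacing registration settings
#'   passed to [register()].
#' @param seed master seed for the stochastic sampler.
#' @param verbose print progress.
#' @return \code{ctavg_template}: list with \code{volume} (the average),
#'   \code{n_controls}, \code{provenance} (ids + transform chains) and
#'   \code{failed}.
#' @export
build_average <- function(controls, fixed_index = 1, ids = NULL,
                          stages = c("rigid", "affine", "bspline"),
                          pyramid = pyramid_config(),
                          sampler = sampler_config(),
                          metric = metric_config(),
                          opt = optimizer_config(),
                          cp_spacing = 20, seed = 17, verbose = FALSE) {
  if (length(controls) < 2) stop("need at least 2 controls")
  lapply(controls, stopifnot_volume)
  if (fixed_index < 1 || fixed_index > length(controls))
    stop("fixed_index out of range")
  if (is.null(ids)) ids <- sprintf("control_%02d", seq_along(controls))
  fixed <- controls[[fixed_index]]
  acc <- array(0, dim(fixed$voxels))
  n_ok <- 0L
  prov <- list()
  failed <- character(0)
  for (i in seq_along(controls)) {
    chain <- tryCatch(
      register(fixed, controls[[i]], stages = stages, pyramid = pyramid,
               sampler = sampler, metric = metric, opt = opt,
               cp_spacing = cp_spacing,
               seed = stage_seed(seed, ids[i]),
               verbose = FALSE),
      error = function(e) {
        warning(sprintf("control %s dropped: %s", ids[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(chain)) {
      failed <- c(failed, ids[i])
      next
    }
    reg <- resample_volume(controls[[i]], chain, fixed, order = 3)
    acc <- acc + reg$voxels
    n_ok <- n_ok + 1L
    prov[[ids[i]]] <- chain
    if (verbose) message(sprintf("registered %s (%d/%d)", ids[i], i,
                                 length(controls)))
  }
  if (n_ok < 2) stop("fewer than 2 controls registered successfully")
  structure(list(volume = volume_hu(acc / n_ok, fixed$spacing,
                                    fixed$origin),
                 n_controls = n_ok, fixed_id = ids[fixed_index],
                 provenance = prov, failed = failed),
            class = "ctavg_template")
}

#' @export
print.ctavg_template <- function(x, ...) {
  cat(sprintf("<ctavg_template> mean of %d controls (fixed: %s)\n",
              x$n_controls, x$fixed_id))
  print(x$volume)
  invisible(x)
}

#' Summarise an average template
#'
#' Reports per-tissue-band mean HU over the template (air < -500, soft
#' tissue, CSF/brain 3-40, blood-range 60-80, bone > 300), the number of
#' contributing controls and any registration failures.
#'
#' @param t a \code{ctavg_template}
#' @param json_path optional path; when given, the report is also written
#'   as JSON.
#' @return the report as a list.
#' @export
template_summary <- function(t, json_path = NULL) {
  v <- t$volume$voxels
  bands <- list(air = v < -500,
                soft = v >= -500 & v < 3,
                brain_csf = v >= 3 & v <= 40,
                blood_range = v >= 60 & v <= 80,
                bone = v > 300)
  band_mean <- lapply(bands, function(m)
    if (any(m)) mean(v[m]) else NA_real_)
  band_vox <- lapply(bands, sum)
  rep <- list(n_controls = t$n_controls, fixed_id = t$fixed_id,
              failed = as.list(t$failed),
              band_mean_hu = band_mean, band_voxels = band_vox)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  rep
}

#' Choose a fixed image automatically
#'
#' Scores each candidate control by the mean mutual information of a cheap
#' coarse-level affine-only alignment to every other control and returns
#' the index with the highest mean (lowest mean cost). Intended for the
#' command-line \code{--fixed auto} mode; the default workflow uses an
#' explicit index.
#'
#' @param controls list of preprocessed \code{ctavg_volume}s
#' @param seed sampler seed
#' @return integer index into \code{controls}
#' @export
select_fixed_auto <- function(controls, seed = 17) {
  n <- length(controls)
  if (n < 2) return(1L)
  pyr <- pyramid_config(levels = 1, sigmas = 4)
  smp <- sampler_config(n_samples = 800, min_valid = 150)
  opt <- optimizer_config(rigid_iters = 100, affine_iters = 100)
  score <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ch <- register(controls[[i]], controls[[j]],
                   stages = c("rigid", "affine"), pyramid = pyr,
                   sampler = smp, opt = opt,
                   seed = derive_seed(seed, i * n + j))
    fx <- controls[[i]]
    smooth <- build_pyramid(fx, pyr)[[1]]
    smooth_m <- build_pyramid(controls[[j]], pyr)[[1]]
    set.seed(derive_seed(seed, i * n + j + 1))
    pts <- sample_coordinates(fx, fx$voxels > -500, 2000)
    p <- chain_parts(ch)
    res <- mi_grad_stage(smooth, 1L, smooth_m, 1L, pts, "none",
                         numeric(0), c(0, 0, 0), global_ = p,
                         want_grad = FALSE)
    score[i, j] <- res$value
  }
  which.max(rowMeans(score, na.rm = TRUE))
}
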