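#' Default pipeline configuration
#'
#' A fully defaulted configuration is valid and carries the study's
#' registration recipe (4 levels, sigma 4/2/1/0.5; 3000 samples, 150
#' minimum; 32 bins; 20 mm control-point spacing; 1500/1500/2500
#' iterations), the default cohort (30 controls; lesion plan
#' 12,2,11,16,3,14,2,1,6 = 67 lesions) and the default detection
#' thresholds (difference 25 HU, blood 60 HU, minimum diameter 2 mm).
#'
#' @return nested named list (serialisable as YAML).
#' @export
default_run_config <- function() {
  list(
    seed = 42,
    out_dir = "ctavg_out",
    fast = TRUE,
    verbose = FALSE,
    phantom = list(n_controls = 30,
                   tbi_plan = c(12, 2, 11, 16, 3, 14, 2, 1, 6),
                   clutter = TRUE, noise_sd = 3),
    preprocess = list(slice_mm = NULL, bone_hu = 300, soft_hu = -200),
    pyramid = list(levels = 4, sigmas = c(4, 2, 1, 0.5)),
    sampler = list(n_samples = 3000, min_valid = 150),
    metric = list(n_bins = 32),
    optimizer = list(rigid_iters = 1500, affine_iters = 1500,
                     bspline_iters = 2500),
    bspline = list(cp_spacing_mm = 20),
    template = list(fixed_index = 1),
    detection = list(diff_threshold = 25, blood_hu_min = 60,
                     min_diameter_mm = 2, overlays = FALSE),
    evaluation = list(max_dist_mm = 5)
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Unknown keys are rejected with the offending field named; missing keys
#' take their defaults; the block-level invariants are enforced by
#' constructing the corresponding configuration objects.
#'
#' @param cfg nested list (e.g. from \code{yaml::read_yaml}).
#' @return the completed configuration.
#' @export
validate_run_config <- function(cfg = list()) {
  def <- default_run_config()
  check <- function(given, defaults, path) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop("unknown config field: ",
           paste0(path, unknown[1]), call. = FALSE)
    out <- defaults
    for (nm in names(given)) {
      if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
        out[[nm]] <- check(given[[nm]], defaults[[nm]],
                           paste0(path, nm, "."))
      } else out[[nm]] <- given[[nm]]
    }
    out
  }
  cfg <- check(cfg, def, "")
  # constructor-level validation (raises with the field's name)
  pyramid_config(cfg$pyramid$levels, cfg$pyramid$sigmas)
  sampler_config(cfg$sampler$n_samples, cfg$sampler$min_valid)
  metric_config(cfg$metric$n_bins)
  optimizer_config(cfg$optimizer$rigid_iters, cfg$optimizer$affine_iters,
                   cfg$optimizer$bspline_iters)
  detection_config(cfg$detection$diff_threshold,
                   cfg$detection$blood_hu_min,
                   cfg$detection$min_diameter_mm)
  if (cfg$evaluation$max_dist_mm <= 0)
    stop("evaluation.max_dist_mm must be > 0", call. = FALSE)
  if (cfg$phantom$n_controls < 2)
    stop("phantom.n_controls must be >= 2", call. = FALSE)
  cfg
}

# per-stage seed derived from the master seed by stable hashing of the
# stage name
stage_seed <- function(master, stage_name) {
  derive_seed(master, sum(utf8ToInt(stage_name)))
}

config_objects <- function(cfg) {
  list(pyramid = pyramid_config(cfg$pyramid$levels, cfg$pyramid$sigmas),
       sampler = sampler_config(cfg$sampler$n_samples,
                                cfg$sampler$min_valid),
       metric = metric_config(cfg$metric$n_bins),
       opt = optimizer_config(cfg$optimizer$rigid_iters,
                              cfg$optimizer$affine_iters,
                              cfg$optimizer$bspline_iters),
       detection = detection_config(cfg$detection$diff_threshold,
                                    cfg$detection$blood_hu_min,
                                    cfg$detection$min_diameter_mm),
       cp_spacing = cfg$bspline$cp_spacing_mm)
}

#' Run the whole pipeline
#'
#' phantom cohort -> preprocessing -> average-template build -> detection on
#' every lesioned subject -> cohort evaluation. All artifacts are written
#' under \code{cfg$out_dir}; \code{manifest.json} records the effective
#' configuration, per-stage seeds and wall times, and
#' \code{cohort_result.json} the (timing-free, reproducible) evaluation.
#'
#' @param cfg configuration list (validated via [validate_run_config()]).
#' @return list(result = \code{ctavg_cohort_result}, paths = list of key
#'   artifact paths), invisibly.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- validate_run_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  co <- config_objects(cfg)
  times <- list()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  spec <- phantom_spec(fast = isTRUE(cfg$fast),
                       clutter = isTRUE(cfg$phantom$clutter),
                       noise_sd = cfg$phantom$noise_sd)

  t0 <- tic()
  say("generating phantom cohort ...")
  coh <- generate_cohort(file.path(out, "data"),
                         n_controls = cfg$phantom$n_controls,
                         tbi_plan = cfg$phantom$tbi_plan,
                         master_seed = stage_seed(cfg$seed, "phantom"),
                         spec = spec)
  times$phantom <- tic() - t0

  t0 <- tic()
  say("preprocessing ...")
  prep <- function(path) {
    v <- read_volume(path)
    preprocess_volume(v, slice_mm = cfg$preprocess$slice_mm,
                      bone_hu = cfg$preprocess$bone_hu,
                      soft_hu = cfg$preprocess$soft_hu)
  }
  controls <- lapply(coh$controls, prep)
  tbis <- lapply(coh$tbi, prep)
  names(tbis) <- sub("\\.nii\\.gz$", "", basename(coh$tbi))
  times$preprocess <- tic() - t0

  t0 <- tic()
  say("building average template from %d controls ...", length(controls))
  tmpl <- build_average(lapply(controls, `[[`, "volume"),
                        fixed_index = cfg$template$fixed_index,
                        pyramid = co$pyramid, sampler = co$sampler,
                        metric = co$metric, opt = co$opt,
                        cp_spacing = co$cp_spacing,
                        seed = stage_seed(cfg$seed, "template"),
                        verbose = isTRUE(cfg$verbose))
  tmpl_path <- file.path(out, "template.nii.gz")
  write_volume(tmpl$volume, tmpl_path)
  template_summary(tmpl, file.path(out, "template_summary.json"))
  times$template <- tic() - t0

  t0 <- tic()
  truth <- read_truth(coh$truth_file)
  subjects <- list()
  for (nm in names(tbis)) {
    say("detecting in %s ...", nm)
    sdir <- file.path(out, "detect", nm)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    det <- detect_lesions(tmpl, tbis[[nm]]$volume, mask = tbis[[nm]]$mask,
                          detection = co$detection,
                          pyramid = co$pyramid, sampler = co$sampler,
                          metric = co$metric, opt = co$opt,
                          cp_spacing = co$cp_spacing,
                          seed = stage_seed(cfg$seed, nm))
    write_volume(volume_hu(det$diff$values, det$diff$spacing,
                           det$diff$origin),
                 file.path(sdir, "difference.nii.gz"))
    write_candidates(det$candidates, file.path(sdir, "candidates.tsv"))
    write_chain(det$chain, file.path(sdir, "chain.txt"))
    if (isTRUE(cfg$detection$overlays))
      render_overlay(tbis[[nm]]$volume, det$diff,
                     file.path(sdir, "overlay"),
                     diff_threshold = co$detection$diff_threshold)
    tr <- truth[truth$subject == nm, , drop = FALSE]
    subjects[[nm]] <- list(candidates = det$candidates,
                           truths = data.frame(z = tr$z, y = tr$y,
                                               x = tr$x))
  }
  times$detect <- tic() - t0

  t0 <- tic()
  res <- evaluate_cohort(subjects, max_dist = cfg$evaluation$max_dist_mm,
                         json_path = file.path(out, "cohort_result.json"))
  times$evaluate <- tic() - t0

  manifest <- list(package = "ctavg",
                   version = as.character(packageVersion("ctavg")),
                   r_version = R.version.string,
                   config = cfg,
                   stage_seeds = list(
                     phantom = stage_seed(cfg$seed, "phantom"),
                     template = stage_seed(cfg$seed, "template")),
                   wall_times_s = times)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(result = res,
                 paths = list(out_dir = out, template = tmpl_path,
                              truth = coh$truth_file,
                              cohort_result = file.path(
                                out, "cohort_result.json"),
                              manifest = file.path(out, "manifest.json"))))
}
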