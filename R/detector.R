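#' Detection configuration
#'
#' Thresholds anchored to CT physiology: CSF and brain parenchyma lie
#' between 3 and 40 HU while fresh blood is generally above 60 HU, so a
#' voxel is a hemorrhage candidate when it is hyperdense in absolute terms
#' (subject HU above \code{blood_hu_min}) and clearly brighter than the
#' deformed average template (\code{diff_threshold}).
#'
#' @param diff_threshold minimum subject-minus-template difference (HU).
#' @param blood_hu_min minimum subject attenuation for blood (HU).
#' @param min_diameter_mm discard components smaller than this
#'   sphere-equivalent diameter.
#' @param max_diameter_mm optional upper size cut (NULL = none).
#' @param connectivity 26 (default) or 6 neighbourhood.
#' @return \code{ctavg_detection_config}
#' @export
detection_config <- function(diff_threshold = 25, blood_hu_min = 60,
                             min_diameter_mm = 2, max_diameter_mm = NULL,
                             connectivity = 26) {
  if (diff_threshold <= 0 || blood_hu_min <= 0 || min_diameter_mm <= 0)
    stop("thresholds must be positive")
  if (!is.null(max_diameter_mm) && max_diameter_mm <= min_diameter_mm)
    stop("max_diameter_mm must exceed min_diameter_mm")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  structure(list(diff_threshold = diff_threshold,
                 blood_hu_min = blood_hu_min,
                 min_diameter_mm = min_diameter_mm,
                 max_diameter_mm = max_diameter_mm,
                 connectivity = as.integer(connectivity)),
            class = "ctavg_detection_config")
}

#' Deform the average template onto a subject scan
#'
#' Full-chain registration with the subject as the fixed image and the
#' template as the moving image, followed by resampling onto the subject
#' grid, giving a template with the subject's dimensions but normal
#' intracranial content.
#'
#' @param template a \code{ctavg_template} or \code{ctavg_volume}.
#' @param subject preprocessed subject \code{ctavg_volume}.
#' @param stages,pyramid,sampler,metric,opt,cp_spacing see [register()].
#' @param seed sampler seed.
#' @return list(volume = aligned template \code{ctavg_volume},
#'   chain = \code{ctavg_chain}).
#' @export
align_template_to_subject <- function(template, subject,
                                      stages = c("rigid", "affine",
                                                 "bspline"),
                                      pyramid = pyramid_config(),
                                      sampler = sampler_config(),
                                      metric = metric_config(),
                                      opt = optimizer_config(),
                                      cp_spacing = 20, seed = 17) {
  tvol <- if (inherits(template, "ctavg_template")) template$volume
          else template
  stopifnot_volume(tvol)
  stopifnot_volume(subject)
  chain <- register(subject, tvol, stages = stages, pyramid = pyramid,
                    sampler = sampler, metric = metric, opt = opt,
                    cp_spacing = cp_spacing, seed = seed)
  list(volume = resample_volume(tvol, chain, subject, order = 3),
       chain = chain)
}

#' Voxelwise subtraction map
#'
#' Signed difference, subject minus aligned template, on the subject grid:
#' only tissue absent from the average remains. Grids must be congruent.
#'
#' @param subject,aligned_template \code{ctavg_volume}s on the same grid.
#' @return \code{ctavg_diffmap}: list(values, spacing, origin).
#' @export
subtract_template <- function(subject, aligned_template) {
  stopifnot_volume(subject)
  stopifnot_volume(aligned_template)
  if (!all(dim(subject$voxels) == dim(aligned_template$voxels)) ||
      max(abs(subject$spacing - aligned_template$spacing)) > 1e-9 ||
      max(abs(subject$origin - aligned_template$origin)) > 1e-6)
    stop("subject and template grids are not congruent")
  structure(list(values = subject$voxels - aligned_template$voxels,
                 spacing = subject$spacing, origin = subject$origin),
            class = "ctavg_diffmap")
}

#' Extract hyperdense lesion candidates from a difference map
#'
#' Thresholds the difference map (difference above \code{diff_threshold}
#' AND subject attenuation above \code{blood_hu_min}) inside the head mask
#' with the skull excluded (subject HU > 300, dilated by one voxel, to
#' suppress skull-edge artifacts), labels 26-connected components, discards
#' those below the minimum sphere-equivalent diameter, and returns
#' candidates sorted by peak difference (ties: voxel count, then
#' lexicographic centroid).
#'
#' @param diff a \code{ctavg_diffmap}
#' @param subject the subject \code{ctavg_volume}
#' @param mask logical head mask (from [strip_externals()]); NULL = all.
#' @param cfg a [detection_config()]
#' @return data.frame: one row per candidate with centroid (z, y, x mm),
#'   equivalent diameter, peak difference, mean subject HU, voxel count.
#' @export
extract_candidates <- function(diff, subject, mask = NULL,
                               cfg = detection_config()) {
  stopifnot(inherits(diff, "ctavg_diffmap"))
  stopifnot_volume(subject)
  d <- dim(subject$voxels)
  if (!all(dim(diff$values) == d))
    stop("difference map and subject grids are not congruent")
  if (is.null(mask)) mask <- array(TRUE, d)
  skull <- subject$voxels > 300
  dim(skull) <- d
  skull <- cpp_dilate(skull, c(1, 1, 1))
  valid <- mask & !skull
  sel <- diff$values > cfg$diff_threshold &
    subject$voxels > cfg$blood_hu_min & valid
  dim(sel) <- d
  empty <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), diameter_mm = numeric(0),
                      peak_diff = numeric(0), mean_hu = numeric(0),
                      voxels = integer(0))
  if (!any(sel)) return(empty)
  lab <- cpp_label3d(sel, cfg$connectivity)
  ncomp <- attr(lab, "ncomp")
  voxvol <- prod(subject$spacing)
  rows <- lapply(seq_len(ncomp), function(b) {
    idx <- which(lab == b)
    nv <- length(idx)
    dia <- (6 * nv * voxvol / pi)^(1 / 3)
    if (dia < cfg$min_diameter_mm) return(NULL)
    if (!is.null(cfg$max_diameter_mm) && dia > cfg$max_diameter_mm)
      return(NULL)
    ai <- arrayInd(idx, d)
    cen <- colMeans(voxel_to_phys(subject, ai))
    data.frame(z = cen[1], y = cen[2], x = cen[3], diameter_mm = dia,
               peak_diff = max(diff$values[idx]),
               mean_hu = mean(subject$voxels[idx]), voxels = nv)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ord <- order(-out$peak_diff, -out$voxels, out$z, out$y, out$x)
  out <- out[ord, , drop = FALSE]
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Run the full detection step for one subject
#'
#' Convenience wrapper: align the template, subtract, extract candidates.
#'
#' @inheritParams align_template_to_subject
#' @param mask head mask for the subject (candidate search region).
#' @param detection a [detection_config()]
#' @return list(candidates, diff, aligned, chain)
#' @export
detect_lesions <- function(template, subject, mask = NULL,
                           detection = detection_config(),
                           stages = c("rigid", "affine", "bspline"),
                           pyramid = pyramid_config(),
                           sampler = sampler_config(),
                           metric = metric_config(),
                           opt = optimizer_config(),
                           cp_spacing = 20, seed = 17) {
  al <- align_template_to_subject(template, subject, stages = stages,
                                  pyramid = pyramid, sampler = sampler,
                                  metric = metric, opt = opt,
                                  cp_spacing = cp_spacing, seed = seed)
  dm <- subtract_template(subject, al$volume)
  cand <- extract_candidates(dm, subject, mask, detection)
  list(candidates = cand, diff = dm, aligned = al$volume,
       chain = al$chain)
}

# blue -> green -> yellow lookup table on |difference|
diff_lut <- function(m, th) {
  s <- pmin(pmax((m - th / 2) / (1.5 * th), 0), 1)
  r <- pmin(pmax(2 * s - 1, 0), 1)
  g <- pmin(2 * s, 1)
  b <- pmin(pmax(1 - 2 * s, 0), 1)
  list(r = r, g = g, b = b)
}

#' Render per-slice colorized overlays
#'
#' One PNG per axial slice: the subject as a grayscale underlay modulating a
#' difference-magnitude lookup table that runs from blue (normal, |diff| at
#' or below half the detection threshold) through green to yellow (at or
#' above twice the threshold), with a colorbar strip embedded at the right
#' edge.
#'
#' @param subject subject \code{ctavg_volume}
#' @param diff a \code{ctavg_diffmap} on the same grid
#' @param out_dir output directory (created if needed)
#' @param diff_threshold the detection threshold anchoring the LUT
#' @param window HU display window for the underlay
#' @return character vector of written file paths, invisibly.
#' @export
render_overlay <- function(subject, diff, out_dir, diff_threshold = 25,
                           window = c(0, 80)) {
  stopifnot_volume(subject)
  stopifnot(inherits(diff, "ctavg_diffmap"))
  d <- dim(subject$voxels)
  if (!all(dim(diff$values) == d)) stop("grids are not congruent")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  nbar <- 8L
  paths <- character(d[1])
  bar_m <- seq(2 * diff_threshold, 0, length.out = d[2])
  bar <- diff_lut(bar_m, diff_threshold)
  for (s in seq_len(d[1])) {
    hu <- subject$voxels[s, , ]
    lum <- pmin(pmax((hu - window[1]) / diff(window), 0), 1)
    lum <- 0.25 + 0.75 * lum
    m <- abs(diff$values[s, , ])
    lut <- diff_lut(as.numeric(m), diff_threshold)
    img <- array(0, c(d[2], d[3] + 2L + nbar, 3))
    img[, seq_len(d[3]), 1] <- lum * lut$r
    img[, seq_len(d[3]), 2] <- lum * lut$g
    img[, seq_len(d[3]), 3] <- lum * lut$b
    for (ch in 1:3)
      img[, d[3] + 2L + seq_len(nbar), ch] <-
        matrix(bar[[c("r", "g", "b")[ch]]], d[2], nbar)
    p <- file.path(out_dir, sprintf("slice_%03d.png", s))
    png::writePNG(img, p)
    paths[s] <- p
  }
  invisible(paths)
}

#' Write a candidate table as TSV
#'
#' Columns: id, x, y, z (mm), diameter_mm, peak_diff, mean_hu, voxels.
#' Note x/y/z are written in column/row/axial order, the conventional
#' reading of the coordinate triplet.
#'
#' @param candidates data.frame from [extract_candidates()]
#' @param path output file
#' @return path, invisibly
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates[, c("id", "x", "y", "z", "diameter_mm", "peak_diff",
                        "mean_hu", "voxels"), drop = FALSE]
  write.table(format(out, digits = 8, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#' @param path TSV file
#' @return data.frame
#' @export
read_candidates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
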