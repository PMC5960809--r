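#' Synthetic head-phantom specification
#'
#' Describes the geometric and intensity model of the synthetic head CT
#' phantoms used as the package's test substrate: an ellipsoidal skull shell
#' around a brain whose cortical gray ribbon, deep gray nuclei, falx and
#' paired CSF-filled ventricles give the registration something to hold on
#' to, with per-subject shape variation (random affine jitter plus a smooth
#' random displacement field) and Gaussian HU noise. Tissue values respect
#' CT physiology: brain and CSF lie within 3-40 HU before noise, bone is
#' about 1000 HU, air -1000 HU, so hyperdense blood (>= 60 HU) is separable
#' by thresholds.
#'
#' @param shape integer length-3 grid size (axial, row, col).
#' @param spacing voxel size mm (default 1 mm isotropic, matching thin-slice
#'   reconstruction); \code{fast = TRUE} switches to a half-resolution
#'   2 mm grid.
#' @param fast logical: half-resolution mode.
#' @param skull_semi,skull_thick outer skull semi-axes and shell thickness
#'   (mm).
#' @param hu_skull,hu_white,hu_gray,hu_csf tissue attenuations (HU).
#' @param ribbon_mm,fold_mm cortical ribbon thickness and folding amplitude
#'   (mm).
#' @param clutter include a detached "pillow" slab (40 HU) beside the head.
#' @param noise_sd Gaussian HU noise standard deviation (0 disables).
#' @param jitter_scale,jitter_rot_deg,jitter_trans_mm half-ranges of the
#'   per-subject affine jitter (scale fraction, degrees, mm).
#' @param warp_amp_mm maximum amplitude of the smooth per-subject
#'   displacement field (mm); the realised amplitude is drawn uniformly from
#'   \code{[warp_amp_mm/3, warp_amp_mm]}.
#' @param warp_grid_mm spacing of the coarse grid the warp is generated on.
#' @return \code{ctavg_phantom_spec}
#' @export
phantom_spec <- function(shape = c(120, 160, 160), spacing = c(1, 1, 1),
                         fast = FALSE,
                         skull_semi = c(52, 70, 60), skull_thick = 7,
                         hu_skull = 1000, hu_white = 35, hu_gray = 40,
                         hu_csf = 8, ribbon_mm = 4, fold_mm = 2,
                         clutter = FALSE, noise_sd = 3,
                         jitter_scale = 0.05, jitter_rot_deg = 5,
                         jitter_trans_mm = 5, warp_amp_mm = 3,
                         warp_grid_mm = 16) {
  if (fast) {
    shape <- c(60, 80, 80)
    spacing <- c(2, 2, 2)
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 skull_semi = skull_semi, skull_thick = skull_thick,
                 hu_skull = hu_skull, hu_white = hu_white,
                 hu_gray = hu_gray, hu_csf = hu_csf,
                 ribbon_mm = ribbon_mm, fold_mm = fold_mm,
                 clutter = clutter, noise_sd = noise_sd,
                 jitter_scale = jitter_scale,
                 jitter_rot_deg = jitter_rot_deg,
                 jitter_trans_mm = jitter_trans_mm,
                 warp_amp_mm = warp_amp_mm, warp_grid_mm = warp_grid_mm),
            class = "ctavg_phantom_spec")
}

#' Lesion specification
#'
#' A small spherical hyperdense lesion. Unset fields (\code{NULL}) are
#' sampled at generation time: the centre uniformly inside the brain at
#' least 3 mm from the inner skull surface (or within 1-3 mm of it when
#' \code{near_bone}), the diameter uniformly in 3-10 mm, and the
#' attenuation from a truncated normal centred at 72 HU (sd 5) clipped to
#' 60-80 HU, the typical range of acute clotted blood. Edges receive a
#' smooth 1-mm feather; the voxel nearest the centre always carries the full
#' lesion HU.
#'
#' @param center subject-frame centre (mm, axial/row/col) or NULL.
#' @param diameter_mm sphere diameter (3-10 mm) or NULL.
#' @param hu lesion attenuation (60-80 HU) or NULL.
#' @param near_bone allow the lesion close to the skull (the hardest
#'   clinical case).
#' @param label free-text lesion type.
#' @return \code{ctavg_lesion_spec}
#' @export
lesion_spec <- function(center = NULL, diameter_mm = NULL, hu = NULL,
                        near_bone = FALSE, label = NULL) {
  if (!is.null(diameter_mm) && (diameter_mm <= 0 || diameter_mm > 30))
    stop("diameter_mm out of range")
  if (!is.null(hu) && (hu < 60 || hu > 80))
    stop("lesion HU must lie in [60, 80]")
  structure(list(center = center, diameter_mm = diameter_mm, hu = hu,
                 near_bone = isTRUE(near_bone), label = label),
            class = "ctavg_lesion_spec")
}

# ---- canonical tissue model ----------------------------------------------

# HU at canonical centred coordinates (vectors cz, cy, cx in mm)
phantom_tissue <- function(cz, cy, cx, spec) {
  so <- spec$skull_semi
  si <- so - spec$skull_thick
  q_out <- (cz / so[1])^2 + (cy / so[2])^2 + (cx / so[3])^2
  q_in <- (cz / si[1])^2 + (cy / si[2])^2 + (cx / si[3])^2
  hu <- rep(-1000, length(cz))
  hu[q_out <= 1] <- spec$hu_skull
  brain <- q_in <= 1
  depth <- (1 - sqrt(pmax(q_in, 0))) * min(si)  # approx mm from inner skull
  thick <- spec$ribbon_mm +
    spec$fold_mm * sin(2 * pi * cy / 40) * cos(2 * pi * cx / 34)
  hu[brain] <- ifelse(depth[brain] < thick[brain], spec$hu_gray,
                      spec$hu_white)
  # deep gray nuclei and falx
  bg1 <- ((cz / 8)^2 + ((cy - 10) / 10)^2 + ((cx - 16) / 6)^2) <= 1
  bg2 <- ((cz / 8)^2 + ((cy - 10) / 10)^2 + ((cx + 16) / 6)^2) <= 1
  falx <- brain & abs(cx) < 1.5 & depth < 20
  hu[brain & (bg1 | bg2)] <- spec$hu_gray
  hu[falx] <- spec$hu_gray
  # paired lateral ventricles (CSF)
  v1 <- (((cz - 2) / 9)^2 + ((cy + 5) / 22)^2 + ((cx - 14) / 7)^2) <= 1
  v2 <- (((cz - 2) / 9)^2 + ((cy + 5) / 22)^2 + ((cx + 14) / 7)^2) <= 1
  hu[brain & (v1 | v2)] <- spec$hu_csf
  if (isTRUE(spec$clutter)) {
    pil <- cy > so[2] + 4 & abs(cx) < 55 & abs(cz) < 45
    hu[pil] <- 40
  }
  hu
}

# canonical landmark table (centred mm): skull poles + ventricle tips
phantom_canonical_landmarks <- function(spec) {
  so <- spec$skull_semi
  rbind(
    pole_zneg = c(-so[1], 0, 0), pole_zpos = c(so[1], 0, 0),
    pole_yneg = c(0, -so[2], 0), pole_ypos = c(0, so[2], 0),
    pole_xneg = c(0, 0, -so[3]), pole_xpos = c(0, 0, so[3]),
    vent_r_ant = c(2, -27, 14), vent_l_ant = c(2, -27, -14),
    vent_r_post = c(2, 17, 14), vent_l_post = c(2, 17, -14))
}

# ---- per-subject deformation ---------------------------------------------

# Draw the subject-to-canonical map G(x) = A(x) + d(x): A inverts a random
# affine jitter about the volume centre; d is a smooth random field stored
# on a coarse grid. Consumes RNG.
draw_subject_deformation <- function(spec, centre, extent) {
  deg <- pi / 180
  scales <- stats::runif(3, 1 - spec$jitter_scale, 1 + spec$jitter_scale)
  angles <- stats::runif(3, -spec$jitter_rot_deg, spec$jitter_rot_deg) * deg
  trans <- stats::runif(3, -spec$jitter_trans_mm, spec$jitter_trans_mm)
  M <- cpp_euler_matrix(angles) %*% diag(scales)
  Minv <- solve(M)

  gs <- spec$warp_grid_mm
  lo <- extent["lo", ] - 2 * gs
  n <- as.integer(ceiling((extent["hi", ] + 2 * gs - lo) / gs)) + 1L
  amp <- stats::runif(1, spec$warp_amp_mm / 3, spec$warp_amp_mm)
  comp <- lapply(1:3, function(i) {
    a <- array(stats::rnorm(prod(n)), n)
    cpp_gauss_smooth(a, rep(1.5, 3))
  })
  nrm <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  sc <- amp / max(nrm, 1e-12)
  comp <- lapply(comp, function(a) a * sc)
  list(M = M, Minv = Minv, trans = trans, centre = centre,
       warp = list(origin = lo, spacing = rep(gs, 3), comp = comp),
       angles = angles, scales = scales, amp = amp)
}

# evaluate d (mm, n x 3) at subject points
warp_eval <- function(def, pts) {
  w <- def$warp
  vapply(1:3, function(i)
    cpp_eval_points(w$comp[[i]], w$spacing, w$origin, 1L, pts),
    numeric(nrow(pts)))
}

# G(x): subject physical points -> canonical physical points
subject_to_canonical <- function(def, pts) {
  pts <- rbind(pts)
  a <- t(def$Minv %*% (t(pts) - def$centre - def$trans)) +
    rep(def$centre, each = nrow(pts))
  d <- warp_eval(def, pts)
  a + d
}

# invert G for isolated points (fixed-point iteration); rows of `can` are
# canonical physical points
canonical_to_subject <- function(def, can) {
  can <- rbind(can)
  ainv <- function(y) t(def$M %*% (t(y) - def$centre)) +
    rep(def$centre + def$trans, each = nrow(y))
  L <- ainv(can)
  for (it in 1:60) {
    d <- warp_eval(def, L)
    Lnew <- ainv(can - d)
    if (max(abs(Lnew - L)) < 1e-9) {
      L <- Lnew
      break
    }
    L <- Lnew
  }
  L
}

grid_coords <- function(spec) {
  d <- spec$shape
  sp <- spec$spacing
  z <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  x <- (seq_len(d[3]) - 1) * sp[3]
  list(Z = rep(z, times = d[2] * d[3]),
       Y = rep(rep(y, each = d[1]), times = d[3]),
       X = rep(x, each = d[1] * d[2]))
}

# shared generator core: returns volume (pre-noise), deformation, noise
phantom_base <- function(spec, seed) {
  set.seed(as.integer(seed))
  d <- spec$shape
  sp <- spec$spacing
  origin <- c(0, 0, 0)
  centre <- origin + (d - 1) * sp / 2
  extent <- rbind(lo = origin, hi = origin + (d - 1) * sp)
  def <- draw_subject_deformation(spec, centre, extent)
  g <- grid_coords(spec)
  pts <- cbind(g$Z, g$Y, g$X)
  can <- subject_to_canonical(def, pts)
  hu <- phantom_tissue(can[, 1] - centre[1], can[, 2] - centre[2],
                       can[, 3] - centre[3], spec)
  vox <- array(hu, d)
  noise <- if (spec$noise_sd > 0)
    array(stats::rnorm(prod(d), 0, spec$noise_sd), d) else NULL
  lm_can <- phantom_canonical_landmarks(spec)
  lm_sub <- canonical_to_subject(def, sweep(lm_can, 2, centre, "+"))
  rownames(lm_sub) <- rownames(lm_can)
  list(vox = vox, spacing = sp, origin = origin, centre = centre,
       def = def, noise = noise, landmarks = lm_sub)
}

#' Generate a lesion-free control phantom
#'
#' Deterministic given \code{seed}. Subject-specific shape variation
#' (affine jitter plus a smooth random warp) is applied; landmark positions
#' (skull poles, ventricle tips) mapped into the subject frame are attached
#' for registration tests, along with the subject deformation itself.
#'
#' @param spec a [phantom_spec()]
#' @param seed integer seed
#' @return \code{list(volume, landmarks, deformation)}; \code{volume} is a
#'   \code{ctavg_volume}, \code{landmarks} an n x 3 matrix of subject-frame
#'   positions (mm).
#' @export
generate_control <- function(spec = phantom_spec(), seed = 1) {
  b <- phantom_base(spec, seed)
  vox <- b$vox
  if (!is.null(b$noise)) vox <- vox + b$noise
  list(volume = volume_hu(vox, b$spacing, b$origin),
       landmarks = b$landmarks, deformation = b$def)
}

# depth (mm) below the inner skull surface at canonical centred coords
canonical_depth <- function(cz, cy, cx, spec) {
  si <- spec$skull_semi - spec$skull_thick
  q_in <- (cz / si[1])^2 + (cy / si[2])^2 + (cx / si[3])^2
  (1 - sqrt(pmax(q_in, 0))) * min(si)
}

# paint one lesion into the voxel array (subject frame, post-deformation)
paint_lesion <- function(vox, spacing, origin, center, diameter, hu,
                         feather_mm = 1) {
  d <- dim(vox)
  r <- diameter / 2
  lo <- pmax(1L, floor((center - r - feather_mm - origin) / spacing) + 1L)
  hi <- pmin(d, ceiling((center + r + feather_mm - origin) / spacing) + 1L)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  pz <- origin[1] + (iz - 1) * spacing[1]
  py <- origin[2] + (iy - 1) * spacing[2]
  px <- origin[3] + (ix - 1) * spacing[3]
  nz <- length(iz); ny <- length(iy); nx <- length(ix)
  DZ <- rep(pz - center[1], times = ny * nx)
  DY <- rep(rep(py - center[2], each = nz), times = nx)
  DX <- rep(px - center[3], each = nz * ny)
  dist <- sqrt(DZ^2 + DY^2 + DX^2)
  w <- numeric(length(dist))
  w[dist <= r - feather_mm] <- 1
  edge <- dist > r - feather_mm & dist < r + feather_mm
  w[edge] <- 0.5 * (1 + cos(pi * (dist[edge] - (r - feather_mm)) /
                              (2 * feather_mm)))
  sub <- vox[iz, iy, ix]
  sub <- sub + (hu - sub) * array(w, c(nz, ny, nx))
  # the voxel nearest the centre always carries the full lesion HU
  ctr <- pmin(pmax(round((center - origin) / spacing) + 1, 1), d)
  sub[ctr[1] - lo[1] + 1, ctr[2] - lo[2] + 1, ctr[3] - lo[3] + 1] <- hu
  vox[iz, iy, ix] <- sub
  vox
}

#' Generate a lesioned ("TBI") phantom with ground truth
#'
#' Builds the same subject as [generate_control()] for the given seed, then
#' paints the requested hyperdense lesions in the subject frame (after the
#' shape deformation), so ground-truth centroids are exact. With an empty
#' lesion list the result is identical to the control. Lesions whose
#' support would collide with the skull are rejected unless flagged
#' \code{near_bone}.
#'
#' @param spec a [phantom_spec()]
#' @param lesions list of [lesion_spec()]s, or an integer count (that many
#'   fully sampled lesions).
#' @param seed integer seed
#' @return \code{list(volume, truth, landmarks, deformation)};
#'   \code{truth} is a data.frame (z, y, x mm, diameter_mm, hu, label).
#' @export
generate_tbi <- function(spec = phantom_spec(), lesions = list(), seed = 1) {
  b <- phantom_base(spec, seed)
  if (is.numeric(lesions) && length(lesions) == 1L)
    lesions <- replicate(lesions, lesion_spec(), simplify = FALSE)
  vox <- b$vox
  truth <- list()
  placed <- matrix(numeric(0), 0, 3)
  placed_r <- numeric(0)
  si_min <- min(spec$skull_semi - spec$skull_thick)
  for (ls in lesions) {
    dia <- if (is.null(ls$diameter_mm)) stats::runif(1, 3, 10)
           else ls$diameter_mm
    hu <- if (is.null(ls$hu)) min(80, max(60, stats::rnorm(1, 72, 5)))
          else ls$hu
    r <- dia / 2
    if (is.null(ls$center)) {
      ok <- FALSE
      for (try in 1:500) {
        u <- stats::runif(3, -1, 1)
        can <- b$centre + u * (spec$skull_semi - spec$skull_thick)
        cc <- can - b$centre
        depth <- canonical_depth(cc[1], cc[2], cc[3], spec)
        want_lo <- if (ls$near_bone) 1 else max(3, r + 1)
        want_hi <- if (ls$near_bone) 3 + r else si_min
        if (depth < want_lo || depth > want_hi) next
        ctr <- canonical_to_subject(b$def, can)[1, ]
        if (nrow(placed) &&
            any(sqrt(rowSums(sweep(placed, 2, ctr)^2)) <
                  placed_r + r + 2)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place lesion inside the brain")
      center <- ctr
    } else {
      center <- as.numeric(ls$center)
      cc <- subject_to_canonical(b$def, rbind(center))[1, ] - b$centre
      depth <- canonical_depth(cc[1], cc[2], cc[3], spec)
      if (depth < 0)
        stop("lesion centre lies outside the brain")
      if (depth < r && !ls$near_bone)
        stop("lesion collides with the skull; set near_bone = TRUE to allow")
    }
    label <- if (!is.null(ls$label)) ls$label
             else if (ls$near_bone) "subdural"
             else sample(c("DAI", "contusion", "subarachnoid"), 1)
    vox <- paint_lesion(vox, b$spacing, b$origin, center, dia, hu)
    placed <- rbind(placed, center)
    placed_r <- c(placed_r, r)
    truth[[length(truth) + 1L]] <-
      data.frame(z = center[1], y = center[2], x = center[3],
                 diameter_mm = dia, hu = hu, label = label)
  }
  if (!is.null(b$noise)) vox <- vox + b$noise
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                           diameter_mm = numeric(0), hu = numeric(0),
                           label = character(0))
  rownames(truth) <- NULL
  list(volume = volume_hu(vox, b$spacing, b$origin), truth = truth,
       landmarks = b$landmarks, deformation = b$def)
}

# stable per-subject seed derived from a master seed (kept below 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 131071 + 7919 * as.numeric(index)) %%
               2147483647)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes \code{controls/} (lesion-free phantoms), \code{tbi/} (lesioned
#' phantoms) and \code{cohort_truth.tsv} under \code{out_dir}. The default
#' lesion plan places 12, 2, 11, 16, 3, 14, 2, 1 and 6 lesions in nine
#' subjects (67 in total); per-subject seeds are derived from the master
#' seed, so a rerun is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param n_controls number of control phantoms (default 30).
#' @param tbi_plan integer vector of per-subject lesion counts.
#' @param master_seed master integer seed.
#' @param spec a [phantom_spec()]
#' @return list with file paths and the pooled truth table, invisibly.
#' @export
generate_cohort <- function(out_dir, n_controls = 30,
                            tbi_plan = c(12, 2, 11, 16, 3, 14, 2, 1, 6),
                            master_seed = 42, spec = phantom_spec()) {
  stopifnot(n_controls >= 1, all(tbi_plan >= 0))
  dir.create(file.path(out_dir, "controls"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "tbi"), recursive = TRUE,
             showWarnings = FALSE)
  ctrl_paths <- character(n_controls)
  for (i in seq_len(n_controls)) {
    g <- generate_control(spec, derive_seed(master_seed, i))
    p <- file.path(out_dir, "controls", sprintf("control_%02d.nii.gz", i))
    write_volume(g$volume, p)
    write_sidecar(sub("\\.nii\\.gz$", ".json", p), g,
                  derive_seed(master_seed, i))
    ctrl_paths[i] <- p
  }
  tbi_paths <- character(length(tbi_plan))
  truth_all <- list()
  for (j in seq_along(tbi_plan)) {
    g <- generate_tbi(spec, tbi_plan[j],
                      derive_seed(master_seed, 1000 + j))
    p <- file.path(out_dir, "tbi", sprintf("tbi_%d.nii.gz", j))
    write_volume(g$volume, p)
    write_sidecar(sub("\\.nii\\.gz$", ".json", p), g,
                  derive_seed(master_seed, 1000 + j))
    tbi_paths[j] <- p
    if (nrow(g$truth)) {
      tr <- g$truth
      tr <- cbind(subject = sprintf("tbi_%d", j),
                  tr[, c("x", "y", "z", "diameter_mm", "label")])
      truth_all[[length(truth_all) + 1L]] <- tr
    }
  }
  truth <- if (length(truth_all)) do.call(rbind, truth_all)
           else data.frame(subject = character(0), x = numeric(0),
                           y = numeric(0), z = numeric(0),
                           diameter_mm = numeric(0), label = character(0))
  tp <- file.path(out_dir, "cohort_truth.tsv")
  write.table(format(truth, digits = 10, trim = TRUE, scientific = FALSE),
              tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(controls = ctrl_paths, tbi = tbi_paths, truth_file = tp,
                 truth = truth))
}

write_sidecar <- function(path, g, seed) {
  side <- list(seed = seed,
               landmarks_mm = as.data.frame(g$landmarks),
               affine_scales = g$deformation$scales,
               affine_angles_rad = g$deformation$angles,
               affine_trans_mm = g$deformation$trans,
               warp_amp_mm = g$deformation$amp)
  if (!is.null(g$truth)) side$lesions <- g$truth
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
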