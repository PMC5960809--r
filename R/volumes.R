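#' @useDynLib ctavg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Construct a Hounsfield-unit volume
#'
#' The package's universal image currency: a 3-D scalar grid of CT
#' intensities in Hounsfield units (HU) on an axis-aligned physical grid.
#' Axis order is fixed as (axial slice, row, column); the physical
#' coordinate (mm) of voxel \code{(i, j, k)} (1-based in R) is
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param voxels 3-D numeric array of intensities (HU). Air is about
#'   -1000 HU; all values must be finite.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class \code{ctavg_volume}.
#' @export
volume_hu <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3-D volume")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxel values must all be finite (no NaN/Inf)")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ctavg_volume")
}

#' @export
print.ctavg_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ctavg_volume> %d x %d x %d voxels (axial x row x col)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3f x %.3f x %.3f mm, origin: (%.2f, %.2f, %.2f) mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ctavg_volume <- function(x) dim(x$voxels)

is_volume <- function(x) inherits(x, "ctavg_volume")

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected a ctavg_volume")
  invisible(x)
}

#' Physical extent of a volume
#'
#' @param vol a \code{ctavg_volume}
#' @return 2 x 3 matrix: physical min/max (mm) of the voxel-centre grid.
#' @export
volume_extent <- function(vol) {
  stopifnot_volume(vol)
  d <- dim(vol$voxels)
  rbind(lo = vol$origin, hi = vol$origin + (d - 1) * vol$spacing)
}

# physical coordinates (n x 3, mm) of the voxel centres listed in `idx`
# (n x 3, 1-based indices)
voxel_to_phys <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read a NIfTI-1 volume as Hounsfield units
#'
#' Accepts 3-D scalar NIfTI files with an axis-aligned, positive-spacing
#' orientation (the form this package writes); the file's scale slope and
#' intercept are honoured by the reader, no further rescaling is applied.
#' Data are rearranged into the package's (axial, row, column) axis order.
#'
#' @param path path to a readable \code{.nii} or \code{.nii.gz} file.
#' @return A \code{ctavg_volume}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected 3-D volume: ", path)
  xf <- RNifti::xform(img)
  lin <- unname(xf[1:3, 1:3])
  diag3 <- diag(lin)
  off <- lin - diag(diag3, 3, 3)
  if (any(abs(off) > 1e-4 * max(abs(diag3))) || any(diag3 <= 0))
    stop("unsupported orientation: expected axis-aligned, positive-spacing ",
         "affine in ", path)
  spacing_xyz <- diag3
  origin_xyz <- unname(xf[1:3, 4])
  # file order (x, y, z) -> internal (axial z, row y, col x)
  vox <- aperm(a, c(3, 2, 1))
  volume_hu(vox, spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}

#' Write a volume as NIfTI-1
#'
#' Written as 32-bit float with a diagonal affine; lossless round trip with
#' [read_volume()] up to float precision.
#'
#' @param vol a \code{ctavg_volume}
#' @param path output path (\code{.nii} or \code{.nii.gz})
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  a <- aperm(vol$voxels, c(3, 2, 1))  # back to (x, y, z) file order
  sp <- rev(vol$spacing)
  org <- rev(vol$origin)
  aff <- diag(4)
  aff[1, 1] <- sp[1]; aff[2, 2] <- sp[2]; aff[3, 3] <- sp[3]
  aff[1:3, 4] <- org
  attr(a, "pixdim") <- sp
  img <- RNifti::asNifti(a, datatype = "float")
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Resample a volume to a new axial slice spacing
#'
#' Reconstructs slices at a target spacing along the axial axis by cubic
#' B-spline interpolation (in-plane sampling unchanged), mimicking thin-slice
#' reconstruction at 1 mm. The physical extent is preserved to within one
#' slice.
#'
#' @details Slices are interpolated with a Catmull-Rom cubic kernel under
#'   anti-symmetric boundary extension, so constants and linear intensity
#'   ramps along the axial axis are reproduced exactly.
#'
#' @param vol a \code{ctavg_volume}
#' @param target_slice_mm desired axial spacing in mm (> 0)
#' @return A \code{ctavg_volume} with axial spacing \code{target_slice_mm}.
#' @export
resample_axial <- function(vol, target_slice_mm) {
  stopifnot_volume(vol)
  if (!is.finite(target_slice_mm) || target_slice_mm <= 0)
    stop("target_slice_mm must be > 0")
  d <- dim(vol$voxels)
  extent <- (d[1] - 1) * vol$spacing[1]
  if (target_slice_mm > max(extent, vol$spacing[1]))
    stop("target slice spacing exceeds the volume's axial extent")
  if (abs(target_slice_mm - vol$spacing[1]) < 1e-12) return(vol)
  n_new <- floor(extent / target_slice_mm + 1e-9) + 1L
  # slice fetch with anti-symmetric (linear-preserving) extension
  slice_at <- function(i) {
    if (i >= 0 && i <= d[1] - 1) return(vol$voxels[i + 1, , ])
    if (i < 0) return(2 * vol$voxels[1, , ] - vol$voxels[1 - i, , ])
    2 * vol$voxels[d[1], , ] - vol$voxels[2 * d[1] - 1 - i, , ]
  }
  vox <- array(0, c(n_new, d[2], d[3]))
  for (s in seq_len(n_new)) {
    u <- (s - 1) * target_slice_mm / vol$spacing[1]
    k <- floor(u)
    t <- u - k
    w <- c(0.5 * (-t + 2 * t^2 - t^3),
           0.5 * (2 - 5 * t^2 + 3 * t^3),
           0.5 * (t + 4 * t^2 - 3 * t^3),
           0.5 * (-t^2 + t^3))
    vox[s, , ] <- w[1] * slice_at(k - 1) + w[2] * slice_at(k) +
      w[3] * slice_at(k + 1) + w[4] * slice_at(k + 2)
  }
  tsp <- c(target_slice_mm, vol$spacing[2], vol$spacing[3])
  volume_hu(vox, spacing = tsp, origin = vol$origin)
}

#' Crop axial slices outside the skull
#'
#' Retains the contiguous axial slice range from the first to the last slice
#' containing bone-density voxels, discarding slices above the skull vertex
#' and below the skull base. The origin is updated so retained voxels keep
#' their physical coordinates.
#'
#' @param vol a \code{ctavg_volume}
#' @param bone_hu_threshold HU above which a voxel counts as bone
#'   (default 300).
#' @return A cropped \code{ctavg_volume}.
#' @export
crop_irrelevant_slices <- function(vol, bone_hu_threshold = 300) {
  stopifnot_volume(vol)
  has_bone <- apply(vol$voxels > bone_hu_threshold, 1, any)
  if (!any(has_bone)) stop("no skull found (no voxels above ",
                           bone_hu_threshold, " HU)")
  lo <- which(has_bone)[1]
  hi <- max(which(has_bone))
  if (lo == 1L && hi == dim(vol$voxels)[1]) return(vol)
  vox <- vol$voxels[lo:hi, , , drop = FALSE]
  org <- vol$origin
  org[1] <- org[1] + (lo - 1) * vol$spacing[1]
  volume_hu(vox, vol$spacing, org)
}

#' Remove external structures (hair, pillows, sheets) by thresholding
#'
#' Keeps the largest 3-D connected component of voxels above a soft-tissue
#' threshold (ties broken in favour of the component nearest the volume
#' centre, since the head is central in head CT), morphologically closed to
#' fill internal cavities. Everything outside the head mask is set to air
#' (-1000 HU); voxels inside the mask are untouched.
#'
#' @param vol a \code{ctavg_volume}
#' @param soft_hu_threshold HU above which a voxel may belong to the head
#'   (default -200).
#' @param close_mm radius (mm) of the ball used for morphological closing.
#' @return \code{list(volume = <stripped volume>, mask = <logical array>)}.
#' @export
strip_externals <- function(vol, soft_hu_threshold = -200, close_mm = 3) {
  stopifnot_volume(vol)
  thr <- vol$voxels > soft_hu_threshold
  if (!any(thr)) stop("no head-like structure above ", soft_hu_threshold,
                      " HU")
  lab <- cpp_label3d(thr, 26L)
  ncomp <- attr(lab, "ncomp")
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie: component whose centroid is nearest the volume centre
      d <- dim(vol$voxels)
      centre <- vol$origin + (d - 1) * vol$spacing / 2
      dist <- vapply(best, function(b) {
        idx <- which(lab == b, arr.ind = TRUE)
        cen <- colMeans(voxel_to_phys(vol, idx))
        sqrt(sum((cen - centre)^2))
      }, numeric(1))
      best <- best[order(dist, best)][1]
    } else best <- best[1]
    mask <- lab == best
  } else {
    mask <- lab == 1L
  }
  dim(mask) <- dim(vol$voxels)
  if (close_mm > 0) {
    r <- pmax(close_mm / vol$spacing, 1e-9)
    mask <- cpp_dilate(mask, r)
    mask <- cpp_erode(mask, r)
  }
  vox <- vol$voxels
  vox[!mask] <- -1000
  list(volume = volume_hu(vox, vol$spacing, vol$origin), mask = mask)
}

#' Preprocess a head CT volume
#'
#' The standard preparation chain: optional axial resampling, cropping of
#' slices outside the skull, and removal of external structures.
#'
#' @param vol a \code{ctavg_volume}
#' @param slice_mm target axial spacing in mm, or \code{NULL} to keep the
#'   native spacing.
#' @param bone_hu bone threshold passed to [crop_irrelevant_slices()].
#' @param soft_hu soft-tissue threshold passed to [strip_externals()].
#' @return \code{list(volume, mask)} as from [strip_externals()].
#' @export
preprocess_volume <- function(vol, slice_mm = NULL, bone_hu = 300,
                              soft_hu = -200) {
  stopifnot_volume(vol)
  if (!is.null(slice_mm)) vol <- resample_axial(vol, slice_mm)
  vol <- crop_irrelevant_slices(vol, bone_hu)
  strip_externals(vol, soft_hu)
}
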