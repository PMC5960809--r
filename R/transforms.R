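#' Transform stages and chains
#'
#' A transform chain maps fixed-image physical points (mm) to moving-image
#' physical points. Global stages (rigid, affine) compose sequentially; the
#' B-spline stage adds a free-form displacement evaluated at the chain input
#' point (the classical global + local decomposition), so its control grid is
#' defined over the fixed-image domain plus a margin. An empty chain is the
#' identity map.
#'
#' @name transforms
NULL

#' Rigid stage (rotation + translation)
#'
#' @param angles Euler angles (rad) about the axial, row and column axes,
#'   applied in that order.
#' @param trans translation (mm).
#' @param center rotation centre (mm), typically the fixed-image head
#'   centroid.
#' @return stage object
#' @export
rigid_stage <- function(angles = c(0, 0, 0), trans = c(0, 0, 0),
                        center = c(0, 0, 0)) {
  structure(list(kind = "rigid", angles = as.numeric(angles),
                 trans = as.numeric(trans), center = as.numeric(center)),
            class = "ctavg_stage")
}

#' Affine stage (linear map + translation about a centre)
#'
#' @param M 3x3 linear map (must be invertible).
#' @param trans translation (mm).
#' @param center centre of the linear map (mm).
#' @return stage object
#' @export
affine_stage <- function(M = diag(3), trans = c(0, 0, 0),
                         center = c(0, 0, 0)) {
  M <- matrix(as.numeric(M), 3, 3)
  if (abs(det(M)) <= 1e-12) stop("affine linear map is singular")
  structure(list(kind = "affine", M = M, trans = as.numeric(trans),
                 center = as.numeric(center)),
            class = "ctavg_stage")
}

#' B-spline free-form deformation stage
#'
#' A regular grid of control-point displacements blended with cubic B-spline
#' basis functions; displacement at any point is the weighted sum of the
#' surrounding 4 x 4 x 4 control points and is identically zero when all
#' coefficients are zero.
#'
#' @param origin physical position (mm) of control point (1,1,1).
#' @param spacing control-point spacing (mm) per axis.
#' @param dim integer length-3 grid dimensions.
#' @param coef 4-D array \code{c(dim, 3)} of displacements (mm); defaults to
#'   all-zero.
#' @return stage object
#' @export
bspline_stage <- function(origin, spacing, dim, coef = NULL) {
  dim <- as.integer(dim)
  if (is.null(coef)) coef <- array(0, c(dim, 3L))
  stopifnot(all(base::dim(coef) == c(dim, 3L)))
  structure(list(kind = "bspline", origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dim = dim, coef = coef),
            class = "ctavg_stage")
}

#' Create a transform chain
#'
#' @param ... stage objects in application order (global stages first, at
#'   most one B-spline stage).
#' @return \code{ctavg_chain} object
#' @export
transform_chain <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && is.list(stages[[1]]) &&
      !inherits(stages[[1]], "ctavg_stage"))
    stages <- stages[[1]]
  kinds <- vapply(stages, function(s) s$kind, character(1))
  if (sum(kinds == "bspline") > 1L)
    stop("at most one B-spline stage per chain")
  structure(list(stages = stages), class = "ctavg_chain")
}

#' @export
print.ctavg_chain <- function(x, ...) {
  kinds <- vapply(x$stages, function(s) s$kind, character(1))
  cat("<ctavg_chain>",
      if (length(kinds)) paste(kinds, collapse = " -> ") else "identity",
      "\n")
  invisible(x)
}

# Collapse the chain into (M, b, bspline-or-NULL) for the C++ evaluators:
# y = M x + b + u(x)
chain_parts <- function(chain) {
  M <- diag(3)
  b <- c(0, 0, 0)
  bs <- NULL
  for (s in chain$stages) {
    if (s$kind == "rigid") {
      R <- cpp_euler_matrix(s$angles)
      # y = R (x - c) + c + t applied after current (M, b)
      b <- as.numeric(R %*% (b - s$center)) + s$center + s$trans
      M <- R %*% M
    } else if (s$kind == "affine") {
      b <- as.numeric(s$M %*% (b - s$center)) + s$center + s$trans
      M <- s$M %*% M
    } else if (s$kind == "bspline") {
      bs <- list(origin = s$origin, spacing = s$spacing, dim = s$dim,
                 coef = s$coef)
    } else stop("unknown stage kind: ", s$kind)
  }
  list(M = M, b = b, bs = bs)
}

#' Apply a transform chain to physical points
#'
#' @param chain a \code{ctavg_chain}
#' @param pts n x 3 matrix of physical points (mm, axis order axial/row/col).
#' @return n x 3 matrix of mapped points.
#' @export
chain_apply <- function(chain, pts) {
  pts <- rbind(pts)
  p <- chain_parts(chain)
  cpp_transform_points(pts, p$M, p$b, p$bs)
}

#' Serialize a transform chain to a plain-text parameter file
#'
#' The format is line-oriented and replayable: a header, then one block per
#' stage carrying its kind, parameter vector and (for B-spline stages) grid
#' metadata.
#'
#' @param chain a \code{ctavg_chain}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_chain <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines("ctavg-chain 1", con)
  for (s in chain$stages) {
    writeLines(paste("stage", s$kind), con)
    if (s$kind == "rigid") {
      writeLines(c(paste("angles", fmt(s$angles)),
                   paste("trans", fmt(s$trans)),
                   paste("center", fmt(s$center))), con)
    } else if (s$kind == "affine") {
      writeLines(c(paste("matrix", fmt(as.numeric(t(s$M)))),
                   paste("trans", fmt(s$trans)),
                   paste("center", fmt(s$center))), con)
    } else if (s$kind == "bspline") {
      writeLines(c(paste("origin", fmt(s$origin)),
                   paste("spacing", fmt(s$spacing)),
                   paste("dim", paste(s$dim, collapse = " ")),
                   paste("coef", fmt(as.numeric(s$coef)))), con)
    }
  }
  invisible(path)
}

#' Read a transform chain written by [write_chain()]
#'
#' @param path parameter file
#' @return \code{ctavg_chain}
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "ctavg-chain"))
    stop("not a ctavg chain file: ", path)
  toks <- strsplit(lines[-1], " +")
  stages <- list()
  cur <- NULL
  flush_stage <- function(cur) {
    if (is.null(cur)) return(NULL)
    switch(cur$kind,
      rigid = rigid_stage(cur$angles, cur$trans, cur$center),
      affine = affine_stage(matrix(cur$matrix, 3, 3, byrow = TRUE),
                            cur$trans, cur$center),
      bspline = bspline_stage(cur$origin, cur$spacing, cur$dim,
                              array(cur$coef, c(cur$dim, 3L))))
  }
  for (tk in toks) {
    if (!length(tk) || tk[1] == "") next
    if (tk[1] == "stage") {
      s <- flush_stage(cur)
      if (!is.null(s)) stages[[length(stages) + 1L]] <- s
      cur <- list(kind = tk[2])
    } else {
      val <- if (tk[1] == "dim") as.integer(tk[-1]) else as.numeric(tk[-1])
      cur[[tk[1]]] <- val
    }
  }
  s <- flush_stage(cur)
  if (!is.null(s)) stages[[length(stages) + 1L]] <- s
  transform_chain(stages)
}

#' Resample a moving volume through a transform chain onto a target grid
#'
#' The output value at fixed voxel x is the interpolated moving-image value
#' at chain(x); points mapping outside the moving domain are filled with air
#' (-1000 HU by default).
#'
#' @param moving a \code{ctavg_volume}
#' @param chain a \code{ctavg_chain} mapping target (fixed) space to moving
#'   space.
#' @param target_grid a \code{ctavg_volume} supplying the output grid.
#' @param order interpolation order: 1 (trilinear) or 3 (cubic B-spline).
#' @param fill fill value for out-of-domain points.
#' @return A \code{ctavg_volume} on the target grid.
#' @export
resample_volume <- function(moving, chain, target_grid, order = 3,
                            fill = -1000) {
  stopifnot_volume(moving)
  stopifnot_volume(target_grid)
  p <- chain_parts(chain)
  src <- if (order == 3) cpp_bspline_prefilter(moving$voxels)
         else moving$voxels
  vox <- cpp_resample_chain(src, moving$spacing, moving$origin,
                            as.integer(order), p$M, p$b, p$bs,
                            as.integer(dim(target_grid$voxels)),
                            target_grid$spacing, target_grid$origin, fill)
  volume_hu(vox, target_grid$spacing, target_grid$origin)
}

#' Interpolate a volume at physical points
#'
#' Order 1 is trilinear; order 3 is cubic B-spline with prefiltered
#' coefficients, reproducing voxel values at voxel centres. Points outside
#' the volume's physical extent yield \code{NA} (an "invalid sample" marker,
#' not an error).
#'
#' @param vol a \code{ctavg_volume}
#' @param pts n x 3 matrix of physical points (mm)
#' @param order 1 or 3
#' @return numeric vector of interpolated HU (NA outside the domain)
#' @export
interpolate_volume <- function(vol, pts, order = 3) {
  stopifnot_volume(vol)
  if (!order %in% c(1, 3)) stop("order must be 1 or 3")
  pts <- rbind(pts)
  src <- if (order == 3) cpp_bspline_prefilter(vol$voxels) else vol$voxels
  cpp_eval_points(src, vol$spacing, vol$origin, as.integer(order), pts)
}
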