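#' Volumetric image or dose grid
#'
#' The common currency of the whole pipeline: a 3D scalar array (HU for
#' images, Gy for dose) with full spatial geometry.  Voxel centers are
#' addressed with 0-based indices; the physical position of voxel
#' \eqn{(i,j,k)} is `origin + axes %*% (i*sx, j*sy, k*sz)` exactly, with
#' `axes` an orthonormal direction matrix whose columns are the patient-frame
#' direction cosines of the three index axes.
#'
#' @param values 3D numeric array.
#' @param origin physical position (mm) of the center of voxel (0,0,0).
#' @param spacing per-axis voxel size in mm, strictly positive.
#' @param axes 3x3 orthonormal direction matrix (default identity).
#' @param frame_id opaque label tying volumes to a common physical frame;
#'   volumes may only be compared or resampled onto each other when their
#'   frames are identical or related by a known rigid transform.
#' @return An object of class `sct_volume`.
#' @export
volume <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                   axes = diag(3), frame_id = "frame-0") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  storage.mode(values) <- "double"
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  axes <- matrix(as.numeric(axes), 3, 3)
  stopifnot(length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive on all axes")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9 ||
      abs(abs(det(axes)) - 1) > 1e-9)
    stop("axes must be orthonormal (|det| = 1)")
  structure(list(values = values, origin = origin, spacing = spacing,
                 axes = axes, frame_id = as.character(frame_id)),
            class = "sct_volume")
}

#' @export
print.sct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sct_volume> %d x %d x %d voxels, spacing %s mm, frame '%s'\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              x$frame_id))
  cat(sprintf("  origin (%s) mm, values in [%s, %s]\n",
              paste(format(x$origin, digits = 6), collapse = ", "),
              format(min(x$values), digits = 6),
              format(max(x$values), digits = 6)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "sct_volume")

#' Extract the spatial geometry of a volume
#'
#' @param x an `sct_volume`.
#' @return A list with `dim`, `origin`, `spacing`, `axes`, `frame_id` --
#'   usable as the `target` of [resample()].
#' @export
volume_geometry <- function(x) {
  list(dim = dim(x$values), origin = x$origin, spacing = x$spacing,
       axes = x$axes, frame_id = x$frame_id)
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (is_volume(a)) volume_geometry(a) else a
  gb <- if (is_volume(b)) volume_geometry(b) else b
  identical(ga$dim, gb$dim) &&
    max(abs(ga$origin - gb$origin)) <= tol &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$axes - gb$axes)) <= tol
}

#' Convert voxel indices to world coordinates (and back)
#'
#' Indices are 0-based and continuous; index (0,0,0) maps exactly onto the
#' volume origin (voxel-center convention).
#'
#' @param x an `sct_volume` or a geometry list.
#' @param idx n x 3 matrix of (possibly fractional) 0-based indices.
#' @return n x 3 matrix of world positions in mm.
#' @export
index_to_world <- function(x, idx) {
  g <- if (is_volume(x)) volume_geometry(x) else x
  idx <- matrix(as.numeric(idx), ncol = 3)
  w <- t(g$axes %*% t(idx * rep(g$spacing, each = nrow(idx))))
  sweep(w, 2, g$origin, "+")
}

#' @rdname index_to_world
#' @param pts n x 3 matrix of world positions in mm.
#' @export
world_to_index <- function(x, pts) {
  g <- if (is_volume(x)) volume_geometry(x) else x
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- sweep(pts, 2, g$origin, "-")
  t(crossprod(g$axes, t(d))) / rep(g$spacing, each = nrow(pts))
}

#' Resample a volume onto a target geometry
#'
#' Trilinear interpolation for scalar dose/HU, nearest neighbour for masks.
#' Voxels of the target grid falling outside the source support receive
#' `fill` (use -1000 for HU volumes, 0 for dose).
#'
#' @param x an `sct_volume`.
#' @param target an `sct_volume` or geometry list defining the output grid.
#' @param mode `"trilinear"` or `"nearest"`.
#' @param fill value for out-of-support voxels.
#' @return An `sct_volume` on the target geometry.
#' @export
resample <- function(x, target, mode = c("trilinear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  g <- if (is_volume(target)) volume_geometry(target) else target
  if (!is.null(g$frame_id) && !identical(g$frame_id, x$frame_id))
    stop(sprintf("unknown frame relation: '%s' vs '%s'",
                 x$frame_id, g$frame_id))
  vals <- cpp_resample_affine(x$values, x$origin, x$spacing, as.numeric(x$axes),
                              as.integer(g$dim), g$origin, g$spacing,
                              as.numeric(g$axes), as.numeric(diag(3)),
                              c(0, 0, 0), mode == "nearest", fill)
  volume(vals, g$origin, g$spacing, g$axes, x$frame_id)
}

#' Structure mask on a volume geometry
#'
#' @param name structure label, e.g. "PTV", "Brain", "Skull".
#' @param mask logical 3D array on the host volume geometry.
#' @param geometry geometry list of the host volume (see [volume_geometry()]).
#' @param source one of `"contour"`, `"threshold"`, `"synthetic"`.
#' @return An object of class `sct_mask`.
#' @export
structure_mask <- function(name, mask, geometry, source = "synthetic") {
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), as.integer(geometry$dim)))
    stop("mask dimensions must match the host volume geometry")
  source <- match.arg(source, c("contour", "threshold", "synthetic"))
  structure(list(name = name, mask = mask, geometry = geometry,
                 source = source, empty = !any(mask)),
            class = "sct_mask")
}

#' @export
print.sct_mask <- function(x, ...) {
  cat(sprintf("<sct_mask> '%s' (%s): %d voxels%s\n", x$name, x$source,
              sum(x$mask), if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Volume of a structure in cubic millimetres
#' @param mask an `sct_mask`.
#' @export
mask_volume_mm3 <- function(mask) {
  sum(mask$mask) * prod(mask$geometry$spacing)
}

# Evaluate with a deterministic, restorable RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
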