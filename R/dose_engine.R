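#' HU-to-relative-density calibration
#'
#' Piecewise-linear lookup, clamped outside the calibration range.  The
#' table must contain (0, 1.0) so water maps to unit density, with strictly
#' increasing HU and non-negative densities.
#'
#' @param points data frame with columns `hu` and `density`.
#' @return A `density_calibration` object.
#' @export
density_calibration <- function(points = data.frame(
    hu = c(-1000, -200, 0, 1000, 3000),
    density = c(0.001, 0.8, 1.0, 1.6, 2.8))) {
  stopifnot(is.data.frame(points), all(c("hu", "density") %in% names(points)))
  if (any(diff(points$hu) <= 0)) stop("HU must be strictly increasing")
  if (any(points$density < 0)) stop("densities must be >= 0")
  if (!any(points$hu == 0 & abs(points$density - 1) < 1e-12))
    stop("calibration must contain the point (0, 1.0)")
  structure(list(points = points), class = "density_calibration")
}

#' @rdname density_calibration
#' @param hu numeric vector (or 3D array) of HU values.
#' @param cal a `density_calibration`.
#' @return `hu_to_density()`: relative densities, same shape as `hu`.
#' @export
hu_to_density <- function(hu, cal = density_calibration()) {
  d <- approx(cal$points$hu, cal$points$density, xout = as.numeric(hu),
              rule = 2)$y
  if (!is.null(dim(hu))) dim(d) <- dim(hu)
  d
}

#' Beam and plan specification for the toy dose engine
#'
#' The engine is a deterministic primary-photon model: exponentially
#' attenuated divergent beams with a flat field inside the aperture, a
#' Gaussian penumbra beyond it and an inverse-square factor.  It is not a
#' clinical dose algorithm; it exists so that two dose grids computed on a
#' CT and an sCT differ in a density-sensitive, reproducible way.
#'
#' @param source_position_mm beam source (world mm).
#' @param isocenter_mm beam isocenter (world mm); must differ from the source.
#' @param aperture_radius_mm field radius at the isocenter plane (> 0).
#' @param weight unitless fluence scale.
#' @param penumbra_sigma_mm lateral Gaussian rolloff beyond the aperture.
#' @return A `beam_spec` list.
#' @export
beam_spec <- function(source_position_mm, isocenter_mm, aperture_radius_mm,
                      weight = 1, penumbra_sigma_mm = 3) {
  if (all(source_position_mm == isocenter_mm))
    stop("source must differ from isocenter")
  if (aperture_radius_mm <= 0) stop("aperture must be > 0")
  structure(list(source_position_mm = as.numeric(source_position_mm),
                 isocenter_mm = as.numeric(isocenter_mm),
                 aperture_radius_mm = aperture_radius_mm, weight = weight,
                 penumbra_sigma_mm = penumbra_sigma_mm),
            class = "beam_spec")
}

#' @rdname beam_spec
#' @param beams list of `beam_spec`.
#' @param prescription_gy prescribed dose D_pres in Gy (> 0).
#' @param mu_eff_per_mm effective linear attenuation coefficient in water.
#' @return `plan_spec()`: a `plan_spec` list.  The normalization rule is
#'   "mean PTV dose on the planning CT equals `prescription_gy`".
#' @export
plan_spec <- function(beams, prescription_gy = 60, mu_eff_per_mm = 0.005) {
  stopifnot(prescription_gy > 0, mu_eff_per_mm > 0, length(beams) >= 1)
  structure(list(beams = beams, prescription_gy = prescription_gy,
                 mu_eff_per_mm = mu_eff_per_mm),
            class = "plan_spec")
}

#' Default four-field coplanar beam arrangement
#'
#' Four beams at 0/90/180/270 degrees in the axial plane, aimed at the PTV
#' centroid with a 1000 mm source-axis distance and an aperture of the PTV
#' bounding radius plus a 5 mm margin.
#'
#' @param ptv an [structure_mask()] for the PTV.
#' @param sad_mm source-axis distance.
#' @param margin_mm aperture margin beyond the PTV radius.
#' @return List of four [beam_spec()].
#' @export
default_plan <- function(ptv, sad_mm = 1000, margin_mm = 5) {
  idx <- which(ptv$mask, arr.ind = TRUE) - 1
  ctr_idx <- colMeans(idx)
  iso <- as.numeric(index_to_world(ptv$geometry, rbind(ctr_idx)))
  w <- index_to_world(ptv$geometry, idx)
  rad <- sqrt(max(rowSums(sweep(w, 2, iso)^2)))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  lapply(seq_len(4), function(b)
    beam_spec(iso + sad_mm * dirs[b, ], iso, rad + margin_mm))
}

#' Water-equivalent path length through a density volume
#'
#' Exact Siddon voxel-boundary traversal: the sum over traversed voxels of
#' geometric intersection length times voxel relative density.
#'
#' @param volume an `sct_volume` of relative densities.
#' @param src ray origin(s), length-3 vector or n x 3 matrix (world mm).
#' @param dst ray endpoint(s), length-3 vector or n x 3 matrix.
#' @return Numeric vector of WEPL in mm (0 for rays missing the grid or
#'   zero-length segments).
#' @export
radiological_path <- function(volume, src, dst) {
  src <- matrix(as.numeric(src), ncol = 3)
  dst <- matrix(as.numeric(dst), ncol = 3)
  cpp_wepl_batch(volume$values, volume$origin, volume$spacing,
                 as.numeric(volume$axes), src, dst)
}

#' Compute the plan dose on an image
#'
#' Raw dose at a voxel is the sum over beams of
#' `weight * exp(-mu_eff * WEPL) * lateral * invsq`.  When `mu_factor` is
#' absent it is chosen so that the mean raw PTV dose scales to the
#' prescription; passing the factor computed on the planning CT back in for
#' an sCT recalculation reproduces the "monitor units unchanged" contract:
#' the scaling is computed once on the CT and reused verbatim.
#'
#' @param image an `sct_volume` in HU.
#' @param plan a [plan_spec()].
#' @param cal a [density_calibration()].
#' @param ptv PTV [structure_mask()]; required when `mu_factor` is `NULL`.
#' @param mu_factor optional precomputed normalization factor.
#' @return list with `dose` (an `sct_volume` in Gy) and `mu_factor`.
#' @export
compute_plan_dose <- function(image, plan, cal = density_calibration(),
                              ptv = NULL, mu_factor = NULL) {
  dens <- hu_to_density(image$values, cal)
  beams <- t(vapply(plan$beams, function(b)
    c(b$source_position_mm, b$isocenter_mm, b$aperture_radius_mm,
      b$weight, b$penumbra_sigma_mm), numeric(9)))
  raw <- cpp_plan_dose(dens, image$origin, image$spacing,
                       as.numeric(image$axes), beams, plan$mu_eff_per_mm)
  if (is.null(mu_factor)) {
    if (is.null(ptv) || ptv$empty)
      stop("a nonempty PTV is required to compute the normalization factor")
    mu_factor <- plan$prescription_gy / mean(raw[ptv$mask])
  }
  dose <- volume(raw * mu_factor, image$origin, image$spacing, image$axes,
                 image$frame_id)
  list(dose = dose, mu_factor = mu_factor)
}
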