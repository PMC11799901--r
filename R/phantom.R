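#' Specification of a synthetic head phantom
#'
#' A digital head standing in for a clinical planning CT: an ellipsoidal
#' head with a bony skull shell, homogeneous brain tissue, an air-filled
#' sinus cavity and a spherical PTV.  HU defaults are textbook values chosen
#' so that the brain/skull threshold windows ([-100, 100] HU and >= 100 HU)
#' recover the planted compartments exactly on the noise-free CT.
#'
#' @param grid_shape voxels per axis (default 96^3).
#' @param spacing_mm voxel size in mm (default 2, matching a 2 mm-slice CT).
#' @param head_semiaxes_mm ellipsoid half-lengths (lateral, AP, cranio-caudal).
#' @param skull_thickness_mm thickness of the bony shell.
#' @param hu_brain,hu_skull,hu_air tissue HU values; `hu_brain` must lie in
#'   [-100, 100] and `hu_skull` must be >= 100.
#' @param sinus_center_mm,sinus_halfwidth_mm air box inside the head (world mm).
#' @param ptv_radius_mm radius of the spherical PTV.
#' @param ptv_placement `"near_sinus"` or `"deep"`; alternatively give
#'   `ptv_center_mm` explicitly.
#' @param ptv_center_mm optional explicit PTV center (overrides placement).
#' @param noise_sigma_hu Gaussian HU noise applied to the sCT inside the body.
#' @param seed integer RNG seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing_mm = c(2, 2, 2),
                         head_semiaxes_mm = c(65, 75, 70),
                         skull_thickness_mm = 6,
                         hu_brain = 30, hu_skull = 800, hu_air = -1000,
                         sinus_center_mm = c(0, -45, -35),
                         sinus_halfwidth_mm = c(16, 14, 12),
                         ptv_radius_mm = 15,
                         ptv_placement = c("deep", "near_sinus"),
                         ptv_center_mm = NULL,
                         noise_sigma_hu = 10, seed = 1L) {
  ptv_placement <- match.arg(ptv_placement)
  if (hu_brain < -100 || hu_brain > 100)
    stop("hu_brain must lie in [-100, 100] so thresholding recovers it")
  if (hu_skull < 100) stop("hu_skull must be >= 100")
  if (is.null(ptv_center_mm))
    ptv_center_mm <- switch(ptv_placement,
      deep = c(0, 10, 5),
      near_sinus = sinus_center_mm +
        c(0, sinus_halfwidth_mm[2] + ptv_radius_mm + 4, 6))
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 head_semiaxes_mm = head_semiaxes_mm,
                 skull_thickness_mm = skull_thickness_mm,
                 hu_brain = hu_brain, hu_skull = hu_skull, hu_air = hu_air,
                 sinus_center_mm = sinus_center_mm,
                 sinus_halfwidth_mm = sinus_halfwidth_mm,
                 ptv_radius_mm = ptv_radius_mm,
                 ptv_placement = ptv_placement,
                 ptv_center_mm = ptv_center_mm,
                 noise_sigma_hu = noise_sigma_hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Planted sCT error modes
#'
#' Declarative description of the failure planted into a synthetic CT pair:
#' `NONE` (faithful up to noise), `SYSTEMATIC_BIAS` (soft-tissue HU offset),
#' `SINUS_MISPREDICTION` (the air sinus filled with soft tissue),
#' `METAL_ARTIFACT` (a high-HU implant with radial streaks, emulating a
#' metal-implant corruption that should fail PSQA), and `BULK_DENSITY`
#' (quantization of the HU map to a few density classes, emulating a
#' bulk-density generator).
#'
#' @param kind one of `"NONE"`, `"SYSTEMATIC_BIAS"`, `"SINUS_MISPREDICTION"`,
#'   `"METAL_ARTIFACT"`, `"BULK_DENSITY"`.
#' @param bias_hu soft-tissue HU offset (`SYSTEMATIC_BIAS`).
#' @param sinus_fill_hu HU that replaces the sinus air (`SINUS_MISPREDICTION`).
#' @param artifact_center_mm,artifact_radius_mm,artifact_amplitude_hu,
#'   streak_radius_mm,streak_amplitude_hu metal implant parameters
#'   (`METAL_ARTIFACT`).
#' @param class_hu,class_thresholds_hu bulk-density class values
#'   (air/soft/bone) and the HU split points (`BULK_DENSITY`).
#' @param soft_shift_hu additive shift of the soft-tissue class value
#'   (`BULK_DENSITY`; the knob [calibrate_bias()] tunes).
#' @return An `error_mode` list.
#' @export
error_mode <- function(kind = c("NONE", "SYSTEMATIC_BIAS",
                                "SINUS_MISPREDICTION", "METAL_ARTIFACT",
                                "BULK_DENSITY"),
                       bias_hu = 25,
                       sinus_fill_hu = 30,
                       artifact_center_mm = NULL, artifact_radius_mm = 10,
                       artifact_amplitude_hu = 3000,
                       streak_radius_mm = 60, streak_amplitude_hu = 300,
                       class_hu = c(air = -1000, soft = 0, bone = 700),
                       class_thresholds_hu = c(-200, 150),
                       soft_shift_hu = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, bias_hu = bias_hu,
                 sinus_fill_hu = sinus_fill_hu,
                 artifact_center_mm = artifact_center_mm,
                 artifact_radius_mm = artifact_radius_mm,
                 artifact_amplitude_hu = artifact_amplitude_hu,
                 streak_radius_mm = streak_radius_mm,
                 streak_amplitude_hu = streak_amplitude_hu,
                 class_hu = class_hu,
                 class_thresholds_hu = class_thresholds_hu,
                 soft_shift_hu = soft_shift_hu),
            class = "error_mode")
}

# planted failure = corruption expected to break dosimetric acceptability
is_planted_failure <- function(mode) {
  mode$kind %in% c("METAL_ARTIFACT", "SINUS_MISPREDICTION", "BULK_DENSITY")
}

# world coordinate arrays of all voxel centers, grid centered on the origin
phantom_coords <- function(spec) {
  d <- spec$grid_shape; s <- spec$spacing_mm
  cx <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * s[1]
  cy <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * s[2]
  cz <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) * s[3]
  list(x = cx, y = cy, z = cz,
       origin = c(cx[1], cy[1], cz[1]))
}

#' Generate one paired CT/sCT phantom
#'
#' The CT is noise-free; the sCT is the CT plus the mode-specific
#' perturbation plus Gaussian HU noise inside the body.  Deterministic for a
#' fixed seed.  The returned ground-truth record states the planted mode and
#' whether the pair is a planted failure.
#'
#' @param spec a [phantom_spec()].
#' @param mode an [error_mode()].
#' @param frame_id frame label shared by the pair.
#' @param pose optional [rigid_pose()]: the phantom is generated already
#'   rigidly moved about `pose_center` (evaluated analytically, so the
#'   moved anatomy is exact rather than resampled).
#' @param pose_center rotation center of `pose` (world mm).
#' @return list with `ct`, `sct` (`sct_volume`), `structures` (named list of
#'   [structure_mask()]: body, brain, skull, ptv, sinus) and `truth`.
#' @export
generate_phantom_pair <- function(spec, mode = error_mode("NONE"),
                                  frame_id = "phantom", pose = NULL,
                                  pose_center = c(0, 0, 0)) {
  d <- spec$grid_shape
  co <- phantom_coords(spec)
  X <- array(co$x, d)
  Y <- array(rep(co$y, each = d[1]), d)
  Z <- array(rep(co$z, each = d[1] * d[2]), d)
  if (!is.null(pose)) {
    q <- pose_invert_points(pose, cbind(as.vector(X), as.vector(Y),
                                        as.vector(Z)), pose_center)
    X <- array(q[, 1], d); Y <- array(q[, 2], d); Z <- array(q[, 3], d)
  }
  a <- spec$head_semiaxes_mm
  r2_out <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2
  ai <- a - spec$skull_thickness_mm
  r2_in <- (X / ai[1])^2 + (Y / ai[2])^2 + (Z / ai[3])^2
  head <- r2_out <= 1
  interior <- r2_in <= 1
  shell <- head & !interior
  sc <- spec$sinus_center_mm; sh <- spec$sinus_halfwidth_mm
  sinus <- interior &
    abs(X - sc[1]) <= sh[1] & abs(Y - sc[2]) <= sh[2] & abs(Z - sc[3]) <= sh[3]
  # asymmetric bony landmarks: without them the head is close to
  # rotationally symmetric and projections carry almost no orientation
  # information (ear canals, a frontal bone ridge, one mastoid-like knob)
  ears <- head & abs(X) >= 35 & sqrt((Y - 5)^2 + (Z + 15)^2) <= 4
  ridge <- interior & abs(X) <= 4 & Y >= -72 & Y <= -52 & Z >= 0 & Z <= 35
  knob <- interior & (X - 38)^2 + (Y - 15)^2 + (Z + 25)^2 <= 7^2
  skull <- (shell | ridge | knob) & !ears
  brain <- interior & !sinus & !ridge & !knob & !ears
  pc <- spec$ptv_center_mm
  ptv <- (X - pc[1])^2 + (Y - pc[2])^2 + (Z - pc[3])^2 <= spec$ptv_radius_mm^2
  if (!any(ptv)) stop("PTV contains no voxels on this grid")
  if (any(ptv & !brain))
    stop("PTV must lie entirely inside the brain compartment")

  hu <- array(spec$hu_air, d)
  hu[brain] <- spec$hu_brain
  hu[skull] <- spec$hu_skull
  hu[sinus] <- spec$hu_air
  geom <- list(dim = d, origin = co$origin, spacing = spec$spacing_mm,
               axes = diag(3), frame_id = frame_id)
  ct <- volume(hu, co$origin, spec$spacing_mm, diag(3), frame_id)

  body <- head
  sct_hu <- apply_error_mode(hu, mode, X, Y, Z, body, brain, sinus, spec)
  if (spec$noise_sigma_hu > 0) {
    noise <- with_seed(spec$seed,
      array(rnorm(prod(d), 0, spec$noise_sigma_hu), d))
    sct_hu[body] <- sct_hu[body] + noise[body]
  }
  sct <- volume(sct_hu, co$origin, spec$spacing_mm, diag(3), frame_id)

  structures <- list(
    body = structure_mask("Body", body, geom),
    brain = structure_mask("Brain", brain, geom),
    skull = structure_mask("Skull", skull, geom),
    ptv = structure_mask("PTV", ptv, geom),
    sinus = structure_mask("Sinus", sinus, geom))
  truth <- list(mode = mode$kind, planted_failure = is_planted_failure(mode),
                seed = spec$seed, ptv_placement = spec$ptv_placement)
  list(ct = ct, sct = sct, structures = structures, truth = truth)
}

apply_error_mode <- function(hu, mode, X, Y, Z, body, brain, sinus, spec) {
  out <- hu
  if (mode$kind == "NONE") {
    # faithful generator: expected sCT - CT difference is zero outside noise
  } else if (mode$kind == "SYSTEMATIC_BIAS") {
    out[brain] <- out[brain] + mode$bias_hu
  } else if (mode$kind == "SINUS_MISPREDICTION") {
    out[sinus] <- mode$sinus_fill_hu
  } else if (mode$kind == "METAL_ARTIFACT") {
    ac <- mode$artifact_center_mm %||% c(0, -35, 5)
    dx <- X - ac[1]; dy <- Y - ac[2]; dz <- Z - ac[3]
    implant <- dx^2 + dy^2 + dz^2 <= mode$artifact_radius_mm^2
    r <- sqrt(dx^2 + dy^2)
    slab <- abs(dz) <= mode$artifact_radius_mm
    streak <- slab & body & !implant & r <= mode$streak_radius_mm
    theta <- atan2(dy, dx)
    # alternating bright/dark radial streaks, strictly nonzero in magnitude
    pattern <- ifelse(cos(8 * theta) >= 0, 1, -1) *
      (1 / 3 + 2 / 3 * abs(cos(8 * theta)))
    out[implant] <- mode$artifact_amplitude_hu
    out[streak] <- pmax(out[streak] +
                          mode$streak_amplitude_hu * pattern[streak], -1000)
  } else if (mode$kind == "BULK_DENSITY") {
    th <- mode$class_thresholds_hu
    cls <- mode$class_hu
    q <- array(cls[["soft"]] + mode$soft_shift_hu, dim(hu))
    q[hu < th[1]] <- cls[["air"]]
    q[hu > th[2]] <- cls[["bone"]]
    out <- q
  }
  out
}

#' Ground-truth artifact support of a METAL_ARTIFACT mode
#'
#' The voxel set (implant sphere plus streak slab inside the body) where the
#' sCT was perturbed, recomputed from the geometry alone.
#'
#' @param spec a [phantom_spec()].
#' @param mode a METAL_ARTIFACT [error_mode()].
#' @return logical 3D array.
#' @export
artifact_support <- function(spec, mode) {
  stopifnot(mode$kind == "METAL_ARTIFACT")
  d <- spec$grid_shape
  co <- phantom_coords(spec)
  X <- array(co$x, d)
  Y <- array(rep(co$y, each = d[1]), d)
  Z <- array(rep(co$z, each = d[1] * d[2]), d)
  a <- spec$head_semiaxes_mm
  body <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2 <= 1
  ac <- mode$artifact_center_mm %||% c(0, -35, 5)
  dx <- X - ac[1]; dy <- Y - ac[2]; dz <- Z - ac[3]
  implant <- dx^2 + dy^2 + dz^2 <= mode$artifact_radius_mm^2
  streak <- abs(dz) <= mode$artifact_radius_mm & body & !implant &
    sqrt(dx^2 + dy^2) <= mode$streak_radius_mm
  implant | streak
}

#' Cohort specification and generation
#'
#' Per-patient seeds are derived deterministically from the master seed so
#' the whole cohort is reproducible; the truth table records every planted
#' failure.
#'
#' @param n_patients cohort size.
#' @param modes named or unnamed list of [error_mode()], one per patient
#'   (recycled `NONE` by default).
#' @param master_seed integer master seed.
#' @param spec_overrides optional list (per patient) of [phantom_spec()]
#'   argument overrides, e.g. `list(`3` = list(ptv_placement = "near_sinus"))`.
#' @param base_spec baseline [phantom_spec()] arguments common to all patients.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, modes = NULL, master_seed = 1L,
                        spec_overrides = list(), base_spec = list()) {
  if (is.null(modes)) modes <- rep(list(error_mode("NONE")), n_patients)
  if (length(modes) != n_patients)
    stop("modes must have one entry per patient")
  ids <- seq_len(n_patients)
  structure(list(n_patients = as.integer(n_patients), patient_ids = ids,
                 modes = modes, master_seed = as.integer(master_seed),
                 spec_overrides = spec_overrides, base_spec = base_spec),
            class = "cohort_spec")
}

# deterministic per-patient seed below 2^31
derive_seed <- function(master_seed, patient_id) {
  as.integer((as.numeric(master_seed) * 7919 + patient_id * 104729 + 17) %%
               2147483647)
}

#' @rdname cohort_spec
#' @param cohort a `cohort_spec`.
#' @return `generate_cohort()`: list with `patients` (each as returned by
#'   [generate_phantom_pair()]) and `truth` (data frame: patient_id, mode,
#'   planted_failure, seed).
#' @export
generate_cohort <- function(cohort) {
  patients <- vector("list", cohort$n_patients)
  rows <- vector("list", cohort$n_patients)
  for (i in cohort$patient_ids) {
    seed_i <- derive_seed(cohort$master_seed, i)
    args <- cohort$base_spec
    ov <- cohort$spec_overrides[[as.character(i)]]
    if (!is.null(ov)) args[names(ov)] <- ov
    args$seed <- seed_i
    spec_i <- do.call(phantom_spec, args)
    pair <- generate_phantom_pair(spec_i, cohort$modes[[i]],
                                  frame_id = sprintf("patient-%02d", i))
    pair$patient_id <- i
    pair$spec <- spec_i
    patients[[i]] <- pair
    rows[[i]] <- data.frame(patient_id = i, mode = pair$truth$mode,
                            planted_failure = pair$truth$planted_failure,
                            seed = seed_i)
  }
  list(patients = patients, truth = do.call(rbind, rows))
}

#' Calibrate the bulk-density soft-tissue shift to a target PTV mean error
#'
#' Finds, by bisection on the soft-tissue HU shift in [-300, 300], the
#' `soft_shift_hu` for which a BULK_DENSITY phantom pair yields a PTV mean
#' error (vs the CT dose, in % of prescription) within `tol_pp` of
#' `target_me_percent`.  Denser soft tissue attenuates more, so negative
#' targets map to positive shifts.
#'
#' @param target_me_percent target ME_PTV in % of prescription (e.g. -1).
#' @param plan a [plan_spec()]; beams default to [default_plan()] on the PTV.
#' @param spec a [phantom_spec()].
#' @param cal a [density_calibration()].
#' @param tol_pp bisection tolerance in percentage points (default 0.2).
#' @param max_iter bisection iteration cap.
#' @return The calibrated shift in HU, with attribute `"me_percent"`.
#' @export
calibrate_bias <- function(target_me_percent, plan = NULL, spec = phantom_spec(),
                           cal = density_calibration(), tol_pp = 0.2,
                           max_iter = 25) {
  if (target_me_percent == 0) return(structure(0, me_percent = 0))
  base_mode <- error_mode("BULK_DENSITY")
  spec0 <- spec
  spec0$noise_sigma_hu <- 0  # calibration on the noise-free signature
  pair0 <- generate_phantom_pair(spec0, error_mode("NONE"))
  if (is.null(plan))
    plan <- plan_spec(beams = default_plan(pair0$structures$ptv))
  ct_dose <- compute_plan_dose(pair0$ct, plan, cal, pair0$structures$ptv)
  me_at <- function(shift) {
    m <- base_mode
    m$soft_shift_hu <- shift
    p <- generate_phantom_pair(spec0, m)
    sd <- compute_plan_dose(p$sct, plan, cal, mu_factor = ct_dose$mu_factor)
    mean_error(sd$dose, ct_dose$dose, pair0$structures$ptv,
               plan$prescription_gy)$percent
  }
  lo <- -300; hi <- 300
  f_lo <- me_at(lo); f_hi <- me_at(hi)
  if ((f_lo - target_me_percent) * (f_hi - target_me_percent) > 0)
    stop(sprintf(
      "target %.2f%% not bracketed by shifts in [-300, 300] HU (ME %.2f%% .. %.2f%%)",
      target_me_percent, f_lo, f_hi))
  mid <- NA_real_; f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- me_at(mid)
    if (abs(f_mid - target_me_percent) <= tol_pp) break
    if ((f_lo - target_me_percent) * (f_mid - target_me_percent) <= 0) {
      hi <- mid; f_hi <- f_mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  structure(mid, me_percent = f_mid)
}
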