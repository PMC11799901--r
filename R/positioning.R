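# Patient-positioning comparison: DRR generation from CT/sCT volumes,
# simulated orthogonal kV pairs at a perturbed patient pose, bone-driven
# 2D/2D rigid registration, 3D rigid registration, and the positioning
# delta with the sCT/CT offset subtracted.
#
# Axis convention (head-first supine): world x = lateral, y = vertical
# (anterior-posterior), z = longitudinal (cranio-caudal).  Poses are
# reported per couch axis (lat, lng, vrt).

#' Rigid pose (couch shift + rotation)
#'
#' Translations in mm and rotations in degrees about the lateral,
#' longitudinal and vertical axes through the isocenter.  The rotation is
#' composed intrinsically in the fixed order lateral, then longitudinal,
#' then vertical.
#'
#' @param translation_mm named or plain length-3 vector (lat, lng, vrt).
#' @param rotation_deg named or plain length-3 vector (lat, lng, vrt),
#'   each in (-180, 180].
#' @return A `rigid_pose` list.
#' @export
rigid_pose <- function(translation_mm = c(0, 0, 0),
                       rotation_deg = c(0, 0, 0)) {
  t <- as.numeric(translation_mm)
  r <- as.numeric(rotation_deg)
  stopifnot(length(t) == 3, length(r) == 3)
  if (any(r <= -180 | r > 180)) stop("rotations must lie in (-180, 180]")
  structure(list(translation_mm = stats::setNames(t, c("lat", "lng", "vrt")),
                 rotation_deg = stats::setNames(r, c("lat", "lng", "vrt"))),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("<rigid_pose> t = (%s) mm, r = (%s) deg [lat, lng, vrt]\n",
              paste(sprintf("%.3f", x$translation_mm), collapse = ", "),
              paste(sprintf("%.3f", x$rotation_deg), collapse = ", ")))
  invisible(x)
}

pose_as_vector <- function(pose) c(pose$translation_mm, pose$rotation_deg)
pose_from_vector <- function(p) rigid_pose(p[1:3], p[4:6])

rot_axis <- function(angle_deg, axis) {
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

# world rotation matrix: intrinsic lateral (x) -> longitudinal (z) ->
# vertical (y)
pose_rotation <- function(pose) {
  r <- pose$rotation_deg
  rot_axis(r[["lat"]], "x") %*% rot_axis(r[["lng"]], "z") %*%
    rot_axis(r[["vrt"]], "y")
}

# world translation vector (x = lat, y = vrt, z = lng)
pose_translation <- function(pose) {
  t <- pose$translation_mm
  c(t[["lat"]], t[["vrt"]], t[["lng"]])
}

# apply the pose to world points: p' = R (p - c) + c + t
pose_apply_points <- function(pose, pts, center = c(0, 0, 0)) {
  R <- pose_rotation(pose)
  tv <- pose_translation(pose)
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(t(R %*% t(sweep(pts, 2, center))), 2, center + tv, "+")
}

pose_invert_points <- function(pose, pts, center = c(0, 0, 0)) {
  R <- pose_rotation(pose)
  tv <- pose_translation(pose)
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(t(crossprod(R, t(sweep(pts, 2, center + tv)))), 2, center, "+")
}

#' Resample a volume under a rigid pose
#'
#' Returns the moved volume sampled on `target` (default: its own grid):
#' `V'(p) = V(P^{-1}(p))` with trilinear interpolation.
#'
#' @param x an `sct_volume`.
#' @param pose a [rigid_pose()].
#' @param center rotation center (world mm), typically the isocenter.
#' @param target target geometry (defaults to the volume's own).
#' @param fill out-of-support fill (use -1000 for HU).
#' @return An `sct_volume` on the target geometry.
#' @export
apply_pose_volume <- function(x, pose, center = c(0, 0, 0), target = NULL,
                              fill = -1000) {
  g <- if (is.null(target)) volume_geometry(x)
       else if (is_volume(target)) volume_geometry(target) else target
  R <- pose_rotation(pose)
  tv <- pose_translation(pose)
  # p_source = R^T (p_target - c - t) + c
  map <- t(R)
  off <- as.numeric(center - map %*% (center + tv))
  vals <- cpp_resample_affine(x$values, x$origin, x$spacing,
                              as.numeric(x$axes), as.integer(g$dim), g$origin,
                              g$spacing, as.numeric(g$axes), as.numeric(map),
                              off, FALSE, fill)
  volume(vals, g$origin, g$spacing, g$axes, x$frame_id)
}

#' Orthogonal two-view projection geometry
#'
#' Two divergent views with sources on the +vertical (anterior) and
#' +lateral axes, flat detectors beyond the isocenter perpendicular to each
#' view axis.
#'
#' @param isocenter_mm isocenter (world mm).
#' @param sad_mm source-isocenter distance.
#' @param det_dist_mm isocenter-detector distance.
#' @param pixel_spacing_mm detector pixel size.
#' @param size_px detector size in pixels (u, v).
#' @return A `projection_geometry` list of two views.
#' @export
projection_geometry <- function(isocenter_mm = c(0, 0, 0), sad_mm = 1000,
                                det_dist_mm = 500, pixel_spacing_mm = 2,
                                size_px = c(128, 128)) {
  view <- function(axis, u, v) {
    list(source = isocenter_mm + sad_mm * axis,
         det_center = isocenter_mm - det_dist_mm * axis,
         u = u, v = v, pixel_spacing_mm = pixel_spacing_mm,
         size_px = as.integer(size_px))
  }
  structure(list(
    isocenter_mm = isocenter_mm,
    views = list(ap = view(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)),
                 lat = view(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))),
    class = "projection_geometry")
}

# world positions of all detector pixel centers of one view
detector_pixels <- function(view) {
  n <- view$size_px
  au <- (seq_len(n[1]) - 1 - (n[1] - 1) / 2) * view$pixel_spacing_mm
  av <- (seq_len(n[2]) - 1 - (n[2] - 1) / 2) * view$pixel_spacing_mm
  offs_u <- outer(au, rep(1, n[2]))
  offs_v <- outer(rep(1, n[1]), av)
  pts <- cbind(as.vector(offs_u), as.vector(offs_v))
  sweep(pts[, 1] %o% view$u + pts[, 2] %o% view$v, 2, view$det_center, "+")
}

# HU volume -> attenuation (relative density) volume for projection;
# air contributes nothing to a radiograph
projection_density <- function(x, bone_weighting, cal) {
  hu <- x$values
  dens <- hu_to_density(hu, cal)
  dens[hu <= -999] <- 0
  if (bone_weighting) dens[hu < 150] <- 0
  volume(dens, x$origin, x$spacing, x$axes, x$frame_id)
}

#' Generate a digitally reconstructed radiograph
#'
#' Each pixel is the line integral of attenuation (relative density from the
#' calibration) along the source-to-pixel ray; with `bone_weighting` the
#' density is zeroed below 150 HU so only bony structures contribute.
#'
#' @param x an `sct_volume` in HU.
#' @param view one view of [projection_geometry()].
#' @param bone_weighting project bone only.
#' @param cal a [density_calibration()].
#' @param pose optional [rigid_pose()] applied to the patient (rendered by
#'   transforming the ray geometry; no volume resampling).
#' @param center rotation center for `pose`.
#' @return Numeric matrix (u x v) of water-equivalent path lengths in mm.
#' @export
generate_drr <- function(x, view, bone_weighting = FALSE,
                         cal = density_calibration(), pose = NULL,
                         center = c(0, 0, 0)) {
  dens <- if (inherits(x, "projection_density_volume")) x
          else projection_density(x, bone_weighting, cal)
  drr_project(dens, view, pose, center)
}

drr_project <- function(dens, view, pose = NULL, center = c(0, 0, 0)) {
  pix <- detector_pixels(view)
  src <- matrix(view$source, 1, 3)
  if (!is.null(pose)) {
    # project the posed patient by inversely posing the ray geometry
    pix <- pose_invert_points(pose, pix, center)
    src <- pose_invert_points(pose, src, center)
  }
  w <- cpp_wepl_batch(dens$values, dens$origin, dens$spacing,
                      as.numeric(dens$axes), src, pix)
  img <- matrix(w, view$size_px[1], view$size_px[2])
  if (all(img == 0))
    warning("DRR is all zero (empty volume or outside the view frustum)")
  img
}

#' Simulate an orthogonal kV image pair at a perturbed patient pose
#'
#' The moved patient is projected in both views with full-density
#' attenuation, and multiplicative Gaussian noise of the stated level is
#' added.  For rigid motion the projection of the moved volume equals the
#' projection of the unmoved volume along inversely-posed rays, so the
#' images are rendered that way -- exact, with no resampling blur.
#' Deterministic per seed.
#'
#' @param ct an `sct_volume` in HU.
#' @param applied_pose the true patient [rigid_pose()] (within +-20 mm/5 deg).
#' @param geom a [projection_geometry()].
#' @param noise_level multiplicative noise standard deviation (fraction).
#' @param seed RNG seed.
#' @param cal a [density_calibration()].
#' @return List of two images (`ap`, `lat`).
#' @export
simulate_kv_pair <- function(ct, applied_pose = rigid_pose(), geom,
                             noise_level = 0.02, seed = 1,
                             cal = density_calibration()) {
  p <- pose_as_vector(applied_pose)
  if (any(abs(p[1:3]) > 20) || any(abs(p[4:6]) > 5))
    stop("applied pose outside +-20 mm / +-5 deg")
  dens <- projection_density(ct, bone_weighting = FALSE, cal)
  imgs <- lapply(geom$views, function(v)
    drr_project(dens, v, applied_pose, geom$isocenter_mm))
  if (noise_level > 0)
    imgs <- with_seed(seed, lapply(imgs, function(im)
      im * (1 + array(rnorm(length(im), 0, noise_level), dim(im)))))
  imgs
}

# halve a view's detector resolution (centered grids stay centered)
coarsen_view <- function(view, f = 2) {
  view$pixel_spacing_mm <- view$pixel_spacing_mm * f
  view$size_px <- view$size_px %/% f
  view
}

# 2x2 block mean (image sides assumed even)
block_mean2 <- function(m) {
  nx <- nrow(m) %/% 2 * 2; ny <- ncol(m) %/% 2 * 2
  m <- m[seq_len(nx), seq_len(ny)]
  0.25 * (m[seq(1, nx, 2), seq(1, ny, 2)] + m[seq(2, nx, 2), seq(1, ny, 2)] +
          m[seq(1, nx, 2), seq(2, ny, 2)] + m[seq(2, nx, 2), seq(2, ny, 2)])
}

# 3x3 box smoothing (replicated edges); damps detector noise before the
# gradient, which would otherwise amplify it into spurious optima
box3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  up <- m[c(1, 1:(nx - 1)), ]; dn <- m[c(2:nx, nx), ]
  h <- (up + m + dn) / 3
  (h[, c(1, 1:(ny - 1))] + h + h[, c(2:ny, ny)]) / 3
}

# central-difference gradient magnitude of the smoothed image
grad_mag <- function(m) {
  m <- box3(m)
  nx <- nrow(m); ny <- ncol(m)
  gx <- m[c(2:nx, nx), ] - m[c(1, 1:(nx - 1)), ]
  gy <- m[, c(2:ny, ny)] - m[, c(1, 1:(ny - 1))]
  sqrt(gx^2 + gy^2)
}

# Nelder-Mead maximization of `fn` as an offset around `start`, giving the
# initial simplex a fixed absolute edge of 0.1 * scale per parameter
nm_offset <- function(start, fn, maxit, scale = 1, reltol = 1e-9) {
  o <- optim(rep(0, length(start)), function(d) -fn(start + d * scale),
             method = "Nelder-Mead",
             control = list(reltol = reltol, maxit = maxit))
  start + o$par * scale
}

ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  cor(as.vector(a), as.vector(b))
}

#' 2D/2D rigid registration of a kV pair against DRRs
#'
#' Finds the 6-parameter couch pose maximizing the mean normalized
#' cross-correlation between the kV pair and DRRs of the posed volume.
#' With `bone_weighting` (the default) the correlation is computed on
#' gradient-magnitude images, in which the high-contrast bony edges
#' dominate -- emulating automatic matching based on bony structures while
#' staying consistent between the kV and DRR renderings.  The search is an
#' iterated per-axis sweep on a 1 mm / 1 deg lattice over +-10 mm / +-5 deg
#' at half resolution, followed by Nelder-Mead refinement at half then full
#' resolution.  A multi-optimum flag is raised when some evaluated pose
#' reaches within 1% of the best similarity while lying more than
#' 2 mm / 2 deg away on any axis.
#'
#' @param kv_pair list of two images as from [simulate_kv_pair()].
#' @param x the `sct_volume` (CT or sCT) to register.
#' @param geom a [projection_geometry()].
#' @param bone_weighting match on bony structures only (default TRUE).
#' @param cal a [density_calibration()].
#' @param trans_range_mm,rot_range_deg,trans_step_mm,rot_step_deg coarse
#'   lattice extent and step.
#' @param sweeps number of coordinate-descent passes.
#' @param similarity_floor below this best NCC the registration is declared
#'   failed.
#' @return A [rigid_pose()] with attributes `similarity`, `multi_optimum`
#'   and `status` (`"ok"` or `"failed"`).
#' @export
register_2d2d <- function(kv_pair, x, geom, bone_weighting = TRUE,
                          cal = density_calibration(), trans_range_mm = 10,
                          rot_range_deg = 5, trans_step_mm = 1,
                          rot_step_deg = 1, sweeps = 2,
                          similarity_floor = 0.2) {
  dens <- projection_density(x, bone_weighting = FALSE, cal)
  views <- geom$views
  # the coarse stage halves only the detector; rays still traverse the
  # full-resolution volume so coarse and fine renderings stay consistent
  # (a downsampled volume renders systematically different DRRs and can
  # pull weakly-constrained rotations degrees away)
  views_c <- lapply(views, coarsen_view, 2)
  kv_c <- lapply(kv_pair, block_mean2)
  ctr <- geom$isocenter_mm
  # bone-driven matching: correlate gradient-magnitude images, where the
  # high-contrast bony edges dominate; otherwise plain intensity NCC
  feat <- if (bone_weighting) grad_mag else identity
  kv_f <- lapply(kv_pair, feat)
  sim_gen <- function(dn, vw, kvf, ft) {
    function(p) {
      pose <- pose_from_vector(p)
      mean(vapply(seq_along(vw), function(i)
        ncc(kvf[[i]], ft(drr_project(dn, vw[[i]], pose, ctr))),
        numeric(1)))
    }
  }
  # coarse stages run on plain intensity: the raw-intensity NCC surface is
  # smooth and single-basin, while edge images develop symmetric secondary
  # optima; the bone-edge criterion only refines at full resolution
  sim_c <- sim_gen(dens, views_c, kv_c, identity)
  sim <- sim_gen(dens, views, kv_f, feat)
  grids <- list(seq(-trans_range_mm, trans_range_mm, by = trans_step_mm),
                seq(-trans_range_mm, trans_range_mm, by = trans_step_mm),
                seq(-trans_range_mm, trans_range_mm, by = trans_step_mm),
                seq(-rot_range_deg, rot_range_deg, by = rot_step_deg),
                seq(-rot_range_deg, rot_range_deg, by = rot_step_deg),
                seq(-rot_range_deg, rot_range_deg, by = rot_step_deg))
  cur <- rep(0, 6)
  evals_p <- list(); evals_s <- numeric(0)
  for (sw in seq_len(sweeps)) {
    for (axis in seq_len(6)) {
      cand <- lapply(grids[[axis]], function(v) { p <- cur; p[axis] <- v; p })
      ss <- vapply(cand, sim_c, numeric(1))
      evals_p <- c(evals_p, cand)
      evals_s <- c(evals_s, ss)
      cur <- cand[[which.max(ss)]]
    }
  }
  # each stage optimizes an offset around the previous solution so the
  # Nelder-Mead start simplex has a fixed absolute size (0.1 unit), then a
  # polish stage shrinks it (x0.2) to settle well below 0.05 mm / 0.05 deg
  o1 <- nm_offset(cur, sim_c, maxit = 200)
  o2 <- nm_offset(o1, sim, maxit = 100)
  best_p <- nm_offset(o2, sim, maxit = 150, scale = 0.2, reltol = 1e-12)
  best_s <- sim(best_p)
  # multi-optimum check over the coarse sweep record
  multi <- FALSE
  if (length(evals_s) > 0) {
    near <- evals_s >= best_s - 0.01 * abs(best_s)
    for (i in which(near)) {
      d <- abs(evals_p[[i]] - best_p)
      if (any(d[1:3] > 2) || any(d[4:6] > 2)) { multi <- TRUE; break }
    }
  }
  out <- pose_from_vector(best_p)
  attr(out, "similarity") <- best_s
  attr(out, "multi_optimum") <- multi
  attr(out, "status") <- if (best_s < similarity_floor) "failed" else "ok"
  out
}

resample_posed <- function(moving, target_geom, pose, center, fill = -1000) {
  R <- pose_rotation(pose)
  tv <- pose_translation(pose)
  map <- t(R)
  off <- as.numeric(center - map %*% (center + tv))
  cpp_resample_affine(moving$values, moving$origin, moving$spacing,
                      as.numeric(moving$axes), as.integer(target_geom$dim),
                      target_geom$origin, target_geom$spacing,
                      as.numeric(target_geom$axes), as.numeric(map), off,
                      FALSE, fill)
}

# separable 3-point box smoothing, `k` passes.  Both registration inputs
# are smoothed so the trilinear kernel implicit in candidate-pose
# resampling (which blurs only the moving volume) no longer biases the
# similarity optimum.
smooth_volume <- function(x, k = 2) {
  a <- x$values
  n <- dim(a)
  for (pass in seq_len(k)) {
    a <- (a[c(1, 1:(n[1] - 1)), , ] + a + a[c(2:n[1], n[1]), , ]) / 3
    a <- (a[, c(1, 1:(n[2] - 1)), ] + a + a[, c(2:n[2], n[2]), ]) / 3
    a <- (a[, , c(1, 1:(n[3] - 1))] + a + a[, , c(2:n[3], n[3])]) / 3
  }
  volume(a, x$origin, x$spacing, x$axes, x$frame_id)
}

downsample_volume <- function(x, f) {
  d <- dim(x$values)
  ix <- seq(1, d[1], by = f); iy <- seq(1, d[2], by = f)
  iz <- seq(1, d[3], by = f)
  volume(x$values[ix, iy, iz], x$origin, x$spacing * f, x$axes, x$frame_id)
}

#' 3D rigid registration by normalized cross-correlation
#'
#' Coarse-to-fine: a translation-only grid search plus Nelder-Mead on a
#' 4x-downsampled grid, then Nelder-Mead refinement at full resolution.
#' The pose maps the moving volume onto the fixed volume's frame.
#'
#' @param moving,fixed `sct_volume`s (HU) with overlapping anatomy.
#' @param center rotation center (defaults to the fixed volume's physical
#'   center).
#' @param coarse_factor downsampling factor of the coarse stage.
#' @param trans_range_mm,trans_step_mm coarse translation search lattice.
#' @param similarity_floor below this best NCC the result is flagged failed.
#' @return A [rigid_pose()] with attributes `similarity` and `status`.
#' @export
register_3d_rigid <- function(moving, fixed, center = NULL,
                              coarse_factor = 4, trans_range_mm = 10,
                              trans_step_mm = 2, similarity_floor = 0.2) {
  if (is.null(center)) {
    d <- dim(fixed$values)
    center <- as.numeric(index_to_world(fixed, rbind((d - 1) / 2)))
  }
  moving <- smooth_volume(moving)
  fixed <- smooth_volume(fixed)
  mov_c <- downsample_volume(moving, coarse_factor)
  fix_c <- downsample_volume(fixed, coarse_factor)
  gc_ <- volume_geometry(fix_c)
  gf <- volume_geometry(fixed)
  fix_c_v <- as.vector(fix_c$values)
  fix_v <- as.vector(fixed$values)
  sim_c <- function(p)
    ncc(fix_c_v, resample_posed(mov_c, gc_, pose_from_vector(p), center))
  sim_f <- function(p)
    ncc(fix_v, resample_posed(moving, gf, pose_from_vector(p), center))
  # translation-only coarse lattice
  tr <- seq(-trans_range_mm, trans_range_mm, by = trans_step_mm)
  best <- c(0, 0, 0); best_s <- -Inf
  for (tx in tr) for (ty in tr) for (tz in tr) {
    s <- sim_c(c(tx, ty, tz, 0, 0, 0))
    if (s > best_s) { best_s <- s; best <- c(tx, ty, tz) }
  }
  o1 <- nm_offset(c(best, 0, 0, 0), sim_c, maxit = 500)
  o2 <- nm_offset(o1, sim_f, maxit = 300, reltol = 1e-10)
  o3 <- nm_offset(o2, sim_f, maxit = 250, scale = 0.2, reltol = 1e-12)
  s3 <- sim_f(o3)
  out <- pose_from_vector(o3)
  attr(out, "similarity") <- s3
  attr(out, "status") <- if (s3 < similarity_floor) "failed" else "ok"
  out
}

#' Positioning difference after sCT/CT offset subtraction
#'
#' Per-axis difference between the sCT-based and CT-based registration
#' results, minus the systematic sCT/CT registration offset, using
#' small-angle additive composition.
#'
#' @param ct_pose,sct_pose [rigid_pose()] from registering the kV pair
#'   against CT-based and sCT-based DRRs.
#' @param sct_ct_offset [rigid_pose()] from the 3D sCT-to-CT registration.
#' @return list with `translation_mm` and `rotation_deg`, per couch axis.
#' @export
positioning_delta <- function(ct_pose, sct_pose,
                              sct_ct_offset = rigid_pose()) {
  list(translation_mm = (sct_pose$translation_mm - ct_pose$translation_mm) -
         sct_ct_offset$translation_mm,
       rotation_deg = (sct_pose$rotation_deg - ct_pose$rotation_deg) -
         sct_ct_offset$rotation_deg)
}

#' Per-fraction positioning study for one CT/sCT pair
#'
#' Simulates `n_fractions` kV pairs from the CT at random true poses
#' (uniform within `pose_range`), registers each pair against the CT and
#' the sCT, subtracts the 3D sCT/CT offset, and tabulates the per-axis
#' deltas.
#'
#' @param ct,sct the paired volumes.
#' @param geom a [projection_geometry()].
#' @param n_fractions number of simulated fractions.
#' @param master_seed seed controlling poses and kV noise.
#' @param pose_range list with `trans_mm` and `rot_deg` maxima.
#' @param noise_level kV noise level.
#' @param ... passed to [register_2d2d()].
#' @return data frame: fraction, axis, kind (shift/rotation), true pose,
#'   CT and sCT registration results, delta.
#' @export
run_positioning_study <- function(ct, sct, geom, n_fractions = 3,
                                  master_seed = 1,
                                  pose_range = list(trans_mm = 5, rot_deg = 3),
                                  noise_level = 0.02, ...) {
  offset <- register_3d_rigid(sct, ct, center = geom$isocenter_mm)
  rows <- list()
  for (fr in seq_len(n_fractions)) {
    seed_fr <- derive_seed(master_seed, fr)
    true_pose <- with_seed(seed_fr, rigid_pose(
      runif(3, -pose_range$trans_mm, pose_range$trans_mm),
      runif(3, -pose_range$rot_deg, pose_range$rot_deg)))
    kv <- simulate_kv_pair(ct, true_pose, geom, noise_level = noise_level,
                           seed = seed_fr + 1)
    ct_pose <- register_2d2d(kv, ct, geom, ...)
    sct_pose <- register_2d2d(kv, sct, geom, ...)
    delta <- positioning_delta(ct_pose, sct_pose, offset)
    for (ax in c("lat", "lng", "vrt")) {
      rows[[length(rows) + 1]] <- data.frame(
        fraction = fr, axis = ax, kind = "shift",
        true_value = true_pose$translation_mm[[ax]],
        ct_value = ct_pose$translation_mm[[ax]],
        sct_value = sct_pose$translation_mm[[ax]],
        delta = delta$translation_mm[[ax]])
      rows[[length(rows) + 1]] <- data.frame(
        fraction = fr, axis = ax, kind = "rotation",
        true_value = true_pose$rotation_deg[[ax]],
        ct_value = ct_pose$rotation_deg[[ax]],
        sct_value = sct_pose$rotation_deg[[ax]],
        delta = delta$rotation_deg[[ax]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
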