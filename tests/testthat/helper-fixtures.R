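# Shared fixtures and independent oracles, all built in code at test time.

# down-scaled head phantom for unit tests (the package default stays 96^3)
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = c(3, 3, 3),
               head_semiaxes_mm = c(55, 65, 60), ptv_radius_mm = 12,
               seed = seed, ...)
}

# smooth correlated random dose pair on an n^3 grid: coarse random field
# upsampled, plus a small multiplicative perturbation on the evaluated dose
random_dose_pair <- function(n, seed, perturb = 0.01, spacing = c(2, 2, 2)) {
  set.seed(seed)
  coarse <- volume(array(runif(5^3, 1, 10), c(5, 5, 5)),
                   spacing = (n - 1) / 4 * spacing, frame_id = "d")
  target <- list(dim = c(n, n, n), origin = c(0, 0, 0), spacing = spacing,
                 axes = diag(3), frame_id = "d")
  ref <- resample(coarse, target)
  ev <- volume(ref$values * (1 + perturb * array(rnorm(n^3), rep(n, 3))),
               ref$origin, ref$spacing, ref$axes, ref$frame_id)
  list(ref = ref, eval = ev)
}

# fine-step ray-marching WEPL oracle (nearest-voxel sampling), independent
# of the Siddon traversal; the step is a small fraction of the voxel size so
# the voxel-boundary quantization error stays well below the tolerance
wepl_oracle <- function(vol, src, dst) {
  L <- sqrt(sum((dst - src)^2))
  if (L == 0) return(0)
  step <- min(vol$spacing) / 500
  nstep <- ceiling(L / step)
  t <- (seq_len(nstep) - 0.5) / nstep
  pts <- outer(t, dst - src) + matrix(src, nstep, 3, byrow = TRUE)
  idx <- round(world_to_index(vol, pts))
  d <- dim(vol$values)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 & idx[, 2] < d[2] &
    idx[, 3] >= 0 & idx[, 3] < d[3]
  dens <- numeric(nstep)
  dens[ok] <- vol$values[idx[ok, , drop = FALSE] + 1]
  sum(dens) * L / nstep
}

# brute-force cumulative-DVH inverse at 0.001 Gy bins: largest tabulated
# dose still covering the requested volume fraction
dvh_oracle <- function(doses, pct) {
  tg <- seq(0, max(doses) + 0.001, by = 0.001)
  srt <- sort(doses)
  n <- length(srt)
  # fraction of voxels receiving >= t, tabulated over the whole bin grid
  frac <- (n - findInterval(tg - 1e-9, srt)) / n
  max(tg[frac >= pct / 100 - 1e-12])
}

# independent even-odd test (angle-summation / winding on a closed polygon
# walked edge by edge), used against the rasterizer's crossing-count rule
point_in_polygon_oracle <- function(px, py, qx, qy) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > qy) != (py[j] > qy)) {
      xint <- px[i] + (qy - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      if (qx < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

expect_pose_close <- function(pose, ref_pose, tol_mm, tol_deg) {
  expect_lt(max(abs(pose$translation_mm - ref_pose$translation_mm)), tol_mm)
  expect_lt(max(abs(pose$rotation_deg - ref_pose$rotation_deg)), tol_deg)
}
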