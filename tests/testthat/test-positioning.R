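test_that("positioning delta arithmetic and antisymmetry are exact", {
  z <- positioning_delta(rigid_pose(c(1, 2, 3), c(0.5, 0, 0)),
                         rigid_pose(c(1, 2, 3), c(0.5, 0, 0)))
  expect_equal(unname(z$translation_mm), c(0, 0, 0))
  expect_equal(unname(z$rotation_deg), c(0, 0, 0))
  d <- positioning_delta(rigid_pose(c(1, 0, 0)), rigid_pose(c(1.8, 0, 0)),
                         rigid_pose(c(0.3, 0, 0)))
  expect_equal(d$translation_mm[["lat"]], 0.5)
  # swapping ct and sct with a negated offset negates the delta
  a <- rigid_pose(c(1, -2, 0.5), c(0.3, -0.1, 1))
  b <- rigid_pose(c(0.2, 1, -1), c(-0.5, 0.4, 0))
  off <- rigid_pose(c(0.1, 0.1, -0.2), c(0, 0.2, -0.1))
  noff <- rigid_pose(-off$translation_mm, -off$rotation_deg)
  d1 <- positioning_delta(a, b, off)
  d2 <- positioning_delta(b, a, noff)
  expect_equal(d1$translation_mm, -d2$translation_mm)
  expect_equal(d1$rotation_deg, -d2$rotation_deg)
  expect_error(rigid_pose(rotation_deg = c(200, 0, 0)), "-180")
})

test_that("DRRs are line integrals: empty volumes, slabs, linearity", {
  geom <- projection_geometry(sad_mm = 1e6, det_dist_mm = 100,
                              pixel_spacing_mm = 2, size_px = c(32, 32))
  air <- volume(array(-1000, c(16, 16, 16)), origin = c(-15, -15, -15),
                spacing = c(2, 2, 2))
  expect_warning(img <- generate_drr(air, geom$views$ap), "frustum")
  expect_true(all(img == 0))
  # 32 mm-thick water cube, near-parallel geometry: interior pixels equal
  # thickness x density
  water <- volume(array(0, c(16, 16, 16)), origin = c(-15, -15, -15),
                  spacing = c(2, 2, 2))
  img_w <- generate_drr(water, geom$views$ap)
  interior <- img_w[12:20, 12:20]
  expect_true(all(abs(interior - 32) / 32 < 5e-3))
  # doubling all densities doubles every pixel exactly
  dens1 <- volume(array(runif(16^3, 0.2, 2), c(16, 16, 16)),
                  origin = c(-15, -15, -15), spacing = c(2, 2, 2))
  dens2 <- volume(dens1$values * 2, dens1$origin, dens1$spacing)
  i1 <- sctqa:::drr_project(dens1, geom$views$lat)
  i2 <- sctqa:::drr_project(dens2, geom$views$lat)
  expect_equal(i2, 2 * i1)
  # bone weighting removes soft tissue from the projection
  soft <- volume(array(30, c(16, 16, 16)), origin = c(-15, -15, -15),
                 spacing = c(2, 2, 2))
  expect_warning(img_b <- generate_drr(soft, geom$views$ap,
                                       bone_weighting = TRUE), "frustum")
  expect_true(all(img_b == 0))
})

test_that("simulated kV pairs are deterministic and shift as projected", {
  p <- generate_phantom_pair(small_spec())
  geom <- projection_geometry(sad_mm = 1e6, det_dist_mm = 100,
                              pixel_spacing_mm = 2, size_px = c(64, 64))
  kv0 <- simulate_kv_pair(p$ct, rigid_pose(), geom, noise_level = 0)
  ref <- generate_drr(p$ct, geom$views$ap)
  expect_equal(kv0$ap, ref, tolerance = 1e-12)
  # pure lateral shift under near-parallel geometry moves the AP image by
  # s / pixel_spacing pixels (cross-correlation peak at 2 px for 4 mm)
  kv4 <- simulate_kv_pair(p$ct, rigid_pose(c(4, 0, 0)), geom,
                          noise_level = 0)
  cors <- vapply(-4:4, function(s)
    cor(as.vector(kv4$ap[(5 + s):(60 + s), ]), as.vector(kv0$ap[5:60, ])),
    numeric(1))
  expect_equal((-4:4)[which.max(cors)], 2)
  a <- simulate_kv_pair(p$ct, rigid_pose(c(1, 2, 0)), geom,
                        noise_level = 0.05, seed = 9)
  b <- simulate_kv_pair(p$ct, rigid_pose(c(1, 2, 0)), geom,
                        noise_level = 0.05, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_kv_pair(p$ct, rigid_pose(c(25, 0, 0)), geom), "20 mm")
})

test_that("3D rigid registration recovers identity and planted poses", {
  p <- generate_phantom_pair(small_spec())
  self <- register_3d_rigid(p$ct, p$ct)
  expect_pose_close(self, rigid_pose(), 0.05, 0.05)
  # NONE-mode sCT is generated co-registered with its CT
  none <- register_3d_rigid(p$sct, p$ct)
  expect_pose_close(none, rigid_pose(), 0.05, 0.05)
  planted <- rigid_pose(c(3, -2, 1.5), c(1, -0.8, 0.6))
  ctr <- c(0, 0, 0)
  # the moved patient is generated analytically at the planted pose, so
  # both volumes are sharp and the registration target is exact
  moved <- generate_phantom_pair(small_spec(), pose = planted,
                                 pose_center = ctr)$ct
  rec <- register_3d_rigid(moved, p$ct, center = ctr)
  # the recovered pose must invert the planted one: applying both in
  # sequence leaves points (within the head radius) fixed
  pts <- matrix(runif(30, -80, 80), 10, 3)
  back <- sctqa:::pose_apply_points(planted,
    sctqa:::pose_apply_points(rec, pts, ctr), ctr)
  expect_lt(max(abs(back - pts)), 0.3)
})

test_that("2D/2D registration self-registers and recovers a planted pose", {
  p <- generate_phantom_pair(small_spec())
  geom <- projection_geometry()
  kv <- simulate_kv_pair(p$ct, rigid_pose(), geom, noise_level = 0)
  self <- register_2d2d(kv, p$ct, geom)
  expect_pose_close(self, rigid_pose(), 0.05, 0.05)
  expect_identical(attr(self, "status"), "ok")
  tp <- rigid_pose(c(2, -1, 3), c(1, 0.5, -0.5))
  kvp <- simulate_kv_pair(p$ct, tp, geom, noise_level = 0.02, seed = 3)
  rec <- register_2d2d(kvp, p$ct, geom)
  expect_pose_close(rec, tp, 0.2, 0.2)
})

test_that("a featureless sphere raises the rotation multi-optimum flag", {
  # uniform water ball: all rotations about its center are equivalent
  n <- 32
  co <- (seq_len(n) - 1 - (n - 1) / 2) * 3
  X <- array(co, c(n, n, n))
  Y <- array(rep(co, each = n), c(n, n, n))
  Z <- array(rep(co, each = n * n), c(n, n, n))
  ball <- array(-1000, c(n, n, n))
  ball[X^2 + Y^2 + Z^2 <= 40^2] <- 0
  v <- volume(ball, origin = rep(co[1], 3), spacing = c(3, 3, 3))
  geom <- projection_geometry(size_px = c(64, 64))
  kv <- simulate_kv_pair(v, rigid_pose(), geom, noise_level = 0)
  reg <- register_2d2d(kv, v, geom)
  expect_true(attr(reg, "multi_optimum"))
})

test_that("kV registration fails loudly without image structure", {
  geom <- projection_geometry(size_px = c(32, 32))
  flat <- list(ap = matrix(1, 32, 32), lat = matrix(1, 32, 32))
  air <- volume(array(-1000, c(16, 16, 16)), origin = c(-15, -15, -15),
                spacing = c(2, 2, 2))
  reg <- suppressWarnings(register_2d2d(flat, air, geom))
  expect_identical(attr(reg, "status"), "failed")
})
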