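test_that("the density calibration is piecewise linear and clamped", {
  cal <- density_calibration()
  expect_equal(hu_to_density(0, cal), 1.0)
  expect_equal(hu_to_density(-1000, cal), min(cal$points$density))
  expect_equal(hu_to_density(-2500, cal), min(cal$points$density))  # clamp
  expect_equal(hu_to_density(5000, cal), max(cal$points$density))
  # midway between two calibration points -> mean of their densities
  expect_equal(hu_to_density(500, cal), (1.0 + 1.6) / 2)
  expect_error(density_calibration(data.frame(hu = c(0, 0),
                                              density = c(1, 1))),
               "increasing")
  expect_error(density_calibration(data.frame(hu = c(-10, 10),
                                              density = c(0.9, 1.1))),
               "\\(0, 1.0\\)")
})

test_that("WEPL is exact on homogeneous cubes and linear in density", {
  water <- volume(array(1, c(50, 50, 50)), origin = c(1, 1, 1),
                  spacing = c(2, 2, 2))
  expect_equal(radiological_path(water, c(-50, 50, 50), c(150, 50, 50)), 100)
  half <- volume(array(0.5, c(50, 50, 50)), origin = c(1, 1, 1),
                 spacing = c(2, 2, 2))
  expect_equal(radiological_path(half, c(-50, 50, 50), c(150, 50, 50)), 50)
  # zero-length segment and a ray missing the grid
  expect_equal(radiological_path(water, c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(radiological_path(water, c(-50, -50, -50), c(-60, -80, -50)), 0)
})

test_that("Siddon traversal matches the fine-step oracle on random grids", {
  set.seed(101)
  for (rep in 1:4) {
    d <- sample(6:9, 3, replace = TRUE)
    sp <- runif(3, 1.5, 3.5)
    g <- volume(array(runif(prod(d), 0.3, 2.0), d),
                origin = runif(3, -5, 5), spacing = sp)
    ctr <- index_to_world(g, rbind((d - 1) / 2))
    for (ray in 1:8) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      jitter <- runif(3, -3, 3)
      src <- as.numeric(ctr) + jitter + u * 35
      dst <- as.numeric(ctr) + jitter - u * 35
      w <- radiological_path(g, src, dst)
      expect_equal(w, wepl_oracle(g, src, dst), tolerance = 1e-3)
    }
  }
})

test_that("scaling all densities by k scales every WEPL by k exactly", {
  set.seed(5)
  g <- volume(array(runif(8^3, 0.2, 2), c(8, 8, 8)), spacing = c(2, 2, 2))
  g3 <- volume(g$values * 3, g$origin, g$spacing)
  src <- c(-20, 3, 5); dst <- c(40, 12, 9)
  expect_equal(radiological_path(g3, src, dst),
               3 * radiological_path(g, src, dst))
})

test_that("central-axis dose follows exp(-mu d) x inverse square in water", {
  # 120 mm water cube, single beam along +x
  n <- 40
  water_hu <- volume(array(0, c(n, n, n)), origin = c(1.5, 1.5, 1.5),
                     spacing = c(3, 3, 3))
  iso <- c(60, 60, 60)
  beam <- beam_spec(iso + c(1000, 0, 0), iso, aperture_radius_mm = 30)
  ptv <- structure_mask("PTV", array(TRUE, c(n, n, n)),
                        volume_geometry(water_hu))
  plan <- plan_spec(list(beam), prescription_gy = 60, mu_eff_per_mm = 0.005)
  res <- compute_plan_dose(water_hu, plan, ptv = ptv)
  # voxels along the central axis (j = k = 20 -> y = z = 60)
  axis_dose <- res$dose$values[, 20, 20]
  x <- 1.5 + (0:(n - 1)) * 3
  dist <- 1060 - x                      # distance from source (at x = 1060)
  depth <- 120 - x                      # water depth from the entry surface
  for (pair in list(c(5, 25), c(10, 35), c(3, 38))) {
    i1 <- pair[1]; i2 <- pair[2]
    expected <- exp(-0.005 * (depth[i1] - depth[i2])) *
      (dist[i2] / dist[i1])^2
    expect_equal(axis_dose[i1] / axis_dose[i2], expected, tolerance = 5e-3)
  }
  # dose x d^2 strictly decreases with water-equivalent depth
  corrected <- axis_dose * dist^2
  expect_true(all(diff(corrected[order(depth)]) < 0))
})

test_that("normalization fixes the mean PTV dose and MU reuse is exact", {
  p <- generate_phantom_pair(small_spec(noise_sigma_hu = 0))
  plan <- plan_spec(default_plan(p$structures$ptv), prescription_gy = 60)
  res <- compute_plan_dose(p$ct, plan, ptv = p$structures$ptv)
  expect_equal(mean(res$dose$values[p$structures$ptv$mask]), 60,
               tolerance = 1e-9)
  # recalculation on an identical sCT with monitor units unchanged is
  # bit-identical
  res2 <- compute_plan_dose(p$ct, plan, mu_factor = res$mu_factor)
  expect_identical(res2$dose$values, res$dose$values)
  expect_error(compute_plan_dose(p$ct, plan), "PTV")
})

test_that("beam and plan invariants are enforced", {
  expect_error(beam_spec(c(0, 0, 0), c(0, 0, 0), 10), "differ")
  expect_error(beam_spec(c(100, 0, 0), c(0, 0, 0), -1), "aperture")
  expect_error(plan_spec(list(), prescription_gy = 60), "length")
  expect_error(plan_spec(list(beam_spec(c(100, 0, 0), c(0, 0, 0), 10)),
                         prescription_gy = -5), "prescription")
})
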