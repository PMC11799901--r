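uniform_dose <- function(value, n = 8, frame = "g") {
  volume(array(value, c(n, n, n)), spacing = c(2, 2, 2), frame_id = frame)
}

test_that("mean error implements the signed voxel-wise average", {
  g <- uniform_dose(2)
  m <- structure_mask("S", array(FALSE, c(8, 8, 8)), volume_geometry(g))
  m$mask[1:3, 1, 1] <- TRUE; m$empty <- FALSE
  ev <- g; ev$values[1:3, 1, 1] <- c(2.02, 2.04, 2.00)
  me <- mean_error(ev, g, m, d_pres = 60)
  expect_equal(me$gy, 0.02)
  expect_equal(me$percent, 100 * 0.02 / 60)   # 0.0333 %
  expect_equal(round(me$percent, 4), 0.0333)
  zero <- mean_error(g, g, m, 60)
  expect_equal(zero$gy, 0); expect_equal(zero$percent, 0)
  # adding a constant shifts ME by exactly that constant
  shifted <- ev; shifted$values <- shifted$values + 0.5
  expect_equal(mean_error(shifted, g, m, 60)$gy, me$gy + 0.5)
  other <- volume(g$values, g$origin, c(1, 1, 1), g$axes, g$frame_id)
  expect_error(mean_error(other, g, m, 60), "one grid")
})

test_that("mean error is antisymmetric and linear on random fields", {
  set.seed(31)
  for (rep in 1:100) {
    n <- 6
    a <- volume(array(runif(n^3, 50, 70), rep(n, 3)), frame_id = "r")
    b <- volume(array(runif(n^3, 50, 70), rep(n, 3)), frame_id = "r")
    msk <- structure_mask("S", array(runif(n^3) < 0.4, rep(n, 3)),
                          volume_geometry(a))
    if (msk$empty) next
    dp <- runif(1, 40, 80)
    me_ab <- mean_error(a, b, msk, dp)
    me_ba <- mean_error(b, a, msk, dp)
    expect_equal(me_ab$gy, -me_ba$gy)
    expect_equal(me_ab$percent, 100 * me_ab$gy / dp)
    met_a <- dvh_metrics(a, msk); met_b <- dvh_metrics(b, msk)
    expect_equal(delta_dx(met_a, met_b, dp), -delta_dx(met_b, met_a, dp))
  }
})

test_that("gamma of identical distributions is zero with full pass rate", {
  set.seed(2)
  ref <- volume(array(runif(10^3, 1, 10), c(10, 10, 10)),
                spacing = c(2, 2, 2), frame_id = "g")
  res <- gamma_map(ref, ref)
  expect_equal(max(res$gamma$values, na.rm = TRUE), 0)
  expect_equal(res$pass_rate, 100)
})

test_that("uniform-field dose scalings give the closed-form gamma", {
  ref <- uniform_dose(4)
  half <- gamma_map(ref, volume(ref$values * 1.005, ref$origin, ref$spacing,
                                ref$axes, ref$frame_id))
  g <- half$gamma$values[!is.na(half$gamma$values)]
  expect_true(all(abs(g - 0.5) <= 1e-9))
  expect_equal(half$pass_rate, 100)
  two <- gamma_map(ref, volume(ref$values * 1.02, ref$origin, ref$spacing,
                               ref$axes, ref$frame_id))
  expect_equal(two$pass_rate, 0)
})

test_that("single-voxel gamma reduces to the pure dose term", {
  one <- function(v) volume(array(v, c(1, 1, 1)), frame_id = "p")
  r <- gamma_bruteforce(one(1.00), one(1.02))
  expect_equal(as.numeric(r$gamma$values), 2.0)   # capped dose-only term
  r2 <- gamma_bruteforce(one(1.00), one(1.005))
  expect_equal(as.numeric(r2$gamma$values), 0.5)
  r3 <- gamma_map(one(1.00), one(1.005))
  expect_equal(as.numeric(r3$gamma$values), 0.5)
})

test_that("pruned gamma equals the exhaustive oracle", {
  for (seed in 1:3) {
    pr <- random_dose_pair(12, seed, perturb = 0.012)
    a <- gamma_map(pr$ref, pr$eval)
    b <- gamma_bruteforce(pr$ref, pr$eval)
    ok <- !is.na(a$gamma$values) & a$gamma$values < 2
    expect_true(any(ok))
    expect_lt(max(abs(a$gamma$values[ok] - b$gamma$values[ok])), 1e-6)
    expect_identical(a$pass_rate, b$pass_rate)
  }
})

test_that("loosening either criterion never lowers the pass rate", {
  pr <- random_dose_pair(10, 77, perturb = 0.02)
  base <- gamma_map(pr$ref, pr$eval, gamma_criteria(1, 1))$pass_rate
  dose_loose <- gamma_map(pr$ref, pr$eval, gamma_criteria(2, 1))$pass_rate
  dta_loose <- gamma_map(pr$ref, pr$eval, gamma_criteria(1, 2))$pass_rate
  expect_gte(dose_loose, base)
  expect_gte(dta_loose, base)
})

test_that("halving the interpolation step never increases any gamma", {
  pr <- random_dose_pair(8, 5, perturb = 0.015)
  coarse <- gamma_map(pr$ref, pr$eval, gamma_criteria(interp_fraction = 0.2))
  fine <- gamma_map(pr$ref, pr$eval, gamma_criteria(interp_fraction = 0.1))
  ok <- !is.na(coarse$gamma$values)
  expect_true(all(fine$gamma$values[ok] <= coarse$gamma$values[ok] + 1e-12))
})

test_that("the 20% threshold governs inclusion", {
  v <- uniform_dose(10)
  v$values[1:2, , ] <- 1            # below 20% of max
  res <- gamma_map(v, v)
  expect_true(all(is.na(res$gamma$values[1:2, , ])))
  expect_true(all(!is.na(res$gamma$values[3:8, , ])))
  low <- uniform_dose(0)
  expect_error(gamma_map(low, low), "threshold")
  off_frame <- volume(v$values, v$origin, v$spacing, v$axes, "other")
  expect_error(gamma_map(v, off_frame), "common frame")
})

test_that("metric_report bundles ME, DVH deltas and gamma for a patient", {
  p <- generate_phantom_pair(small_spec())
  plan <- plan_spec(default_plan(p$structures$ptv))
  ct <- compute_plan_dose(p$ct, plan, ptv = p$structures$ptv)
  sct <- compute_plan_dose(p$sct, plan, mu_factor = ct$mu_factor)
  structures <- list(ptv = p$structures$ptv, brain = p$structures$brain,
                     skull = p$structures$skull)
  row <- metric_report(1, "CT", sct$dose, ct$dose, structures, 60)
  expect_equal(row$reference, "CT")
  expect_lt(abs(row$me_ptv_pct), 0.5)
  expect_gt(row$gamma_pass_pct, 95)
  expect_true(all(c("delta_d2_pct", "delta_dmean_pct") %in% names(row)))
})
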