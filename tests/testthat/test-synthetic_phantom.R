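test_that("a faithful noise-free sCT is identical to its CT", {
  p <- generate_phantom_pair(small_spec(noise_sigma_hu = 0),
                             error_mode("NONE"))
  expect_identical(p$sct$values, p$ct$values)
  expect_false(p$truth$planted_failure)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom_pair(small_spec(seed = 7), error_mode("NONE"))
  b <- generate_phantom_pair(small_spec(seed = 7), error_mode("NONE"))
  expect_identical(a$sct$values, b$sct$values)
  c <- generate_phantom_pair(small_spec(seed = 8), error_mode("NONE"))
  expect_false(identical(a$sct$values, c$sct$values))
})

test_that("metal artifact perturbs the sCT exactly on its support", {
  spec <- small_spec(noise_sigma_hu = 0)
  mode <- error_mode("METAL_ARTIFACT")
  p <- generate_phantom_pair(spec, mode)
  diff <- p$sct$values - p$ct$values
  supp <- artifact_support(spec, mode)
  expect_true(all(diff[supp] != 0))
  expect_true(all(diff[!supp] == 0))
  expect_true(p$truth$planted_failure)
  expect_true(all(p$sct$values >= -1000))
})

test_that("thresholding the noise-free CT recovers the planted masks", {
  p <- generate_phantom_pair(small_spec(noise_sigma_hu = 0))
  th <- threshold_structures(p$ct)
  expect_identical(th$brain$mask, p$structures$brain$mask)
  expect_identical(th$skull$mask, p$structures$skull$mask)
  # the threshold body is the planted outline minus internal air cavities
  expect_true(all(th$body$mask[p$structures$brain$mask]))
  expect_true(all(th$body$mask[p$structures$skull$mask]))
  expect_false(any(th$body$mask & !p$structures$body$mask))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(hu_brain = 300), "hu_brain")
  expect_error(phantom_spec(hu_skull = 50), "hu_skull")
  # PTV poking into the skull shell
  bad <- small_spec(ptv_center_mm = c(0, 55, 0))
  expect_error(generate_phantom_pair(bad), "inside the brain")
})

test_that("bulk density quantizes to the class values", {
  p <- generate_phantom_pair(small_spec(noise_sigma_hu = 0),
                             error_mode("BULK_DENSITY", soft_shift_hu = 40))
  expect_setequal(unique(as.vector(p$sct$values)), c(-1000, 40, 700))
})

test_that("cohorts are reproducible with planted-failure bookkeeping", {
  modes <- c(rep(list(error_mode("NONE")), 3),
             list(error_mode("METAL_ARTIFACT"), error_mode("BULK_DENSITY")))
  cs <- cohort_spec(5, modes, master_seed = 11,
                    base_spec = list(grid_shape = c(48, 48, 48),
                                     spacing_mm = c(3, 3, 3),
                                     head_semiaxes_mm = c(55, 65, 60),
                                     ptv_radius_mm = 12))
  a <- generate_cohort(cs)
  expect_equal(sum(a$truth$planted_failure), 2)
  expect_equal(a$truth$mode[4], "METAL_ARTIFACT")
  expect_false(anyDuplicated(a$truth$patient_id) > 0)
  expect_false(anyDuplicated(a$truth$seed) > 0)
  b <- generate_cohort(cs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients[[4]]$sct$values, b$patients[[4]]$sct$values)
  # an all-NONE cohort has no planted failures
  c0 <- generate_cohort(cohort_spec(3, master_seed = 2,
                                    base_spec = cs$base_spec))
  expect_equal(sum(c0$truth$planted_failure), 0)
})

test_that("per-patient spec overrides reach the generator", {
  cs <- cohort_spec(2, master_seed = 3,
                    base_spec = list(grid_shape = c(48, 48, 48),
                                     spacing_mm = c(3, 3, 3),
                                     head_semiaxes_mm = c(55, 65, 60),
                                     ptv_radius_mm = 12),
                    spec_overrides = list(
                      `2` = list(ptv_placement = "near_sinus")))
  g <- generate_cohort(cs)
  expect_identical(g$patients[[1]]$spec$ptv_placement, "deep")
  expect_identical(g$patients[[2]]$spec$ptv_placement, "near_sinus")
})
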