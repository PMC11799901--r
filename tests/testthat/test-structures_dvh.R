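make_dose <- function(values) {
  v <- volume(array(values, c(length(values), 1, 1)), spacing = c(1, 1, 1),
              frame_id = "d")
  m <- structure_mask("S", array(TRUE, dim(v$values)), volume_geometry(v))
  list(dose = v, mask = m)
}

test_that("threshold windows follow the stated HU rules", {
  # a body blob containing the probe HU values, surrounded by exterior air
  vals <- array(-1000, c(7, 7, 7))
  vals[2:6, 2:6, 2:6] <- 20                  # connected body
  vals[3, 3, 3] <- 50    # brain only
  vals[4, 3, 3] <- 150   # skull only
  vals[5, 3, 3] <- 100   # boundary: member of BOTH brain and skull
  vals[4, 5, 3] <- -500  # internal air pocket: neither
  ct <- volume(vals, spacing = c(1, 1, 1))
  th <- threshold_structures(ct)
  expect_true(th$brain$mask[3, 3, 3]);  expect_false(th$skull$mask[3, 3, 3])
  expect_false(th$brain$mask[4, 3, 3]); expect_true(th$skull$mask[4, 3, 3])
  expect_true(th$brain$mask[5, 3, 3]);  expect_true(th$skull$mask[5, 3, 3])
  expect_false(th$brain$mask[4, 5, 3]); expect_false(th$skull$mask[4, 5, 3])
  # exterior air is never part of a structure
  expect_false(any(th$brain$mask[1, , ]))
  expect_error(threshold_structures(volume(array(-1000, c(3, 3, 3)))),
               "no voxels above")
})

test_that("uniform and endpoint DVH cases are exact", {
  u <- make_dose(rep(2, 64))
  h <- dvh(u$dose, u$mask)
  expect_equal(dose_at_volume(h, 2), 2)
  expect_equal(dose_at_volume(h, 95), 2)
  expect_equal(dose_at_volume(h, 98), 2)
  expect_equal(mean_dose(h), 2)
  q <- make_dose(c(1, 2, 3, 4))
  hq <- dvh(q$dose, q$mask)
  expect_equal(dose_at_volume(hq, 100), 1)   # D100% = minimum voxel dose
  expect_equal(dose_at_volume(hq, 50), 3)    # k/N rule: fraction 0.5 -> d_2
  expect_equal(dose_at_volume(hq, 10), 4)    # below 100/N -> maximum dose
  expect_equal(mean_dose(hq), 2.5)
  expect_error(dose_at_volume(hq, 0), "pct")
  expect_error(dose_at_volume(hq, 101), "pct")
})

test_that("dose_at_volume agrees with the cumulative-histogram oracle", {
  set.seed(42)
  for (rep in 1:10) {
    doses <- runif(20000, 59, 61)
    m <- make_dose(doses)
    h <- dvh(m$dose, m$mask)
    for (pct in c(2, 25, 50, 75, 95, 98)) {
      expect_lt(abs(dose_at_volume(h, pct) - dvh_oracle(doses, pct)),
                0.001 + 1e-9)
    }
  }
})

test_that("DVH metrics are ordered and invariant under voxel reordering", {
  set.seed(9)
  for (rep in 1:20) {
    doses <- rgamma(200, shape = 20, rate = 1 / 3)
    m <- make_dose(doses)
    h <- dvh(m$dose, m$mask)
    d2 <- dose_at_volume(h, 2); d98 <- dose_at_volume(h, 98)
    expect_gte(d2, mean_dose(h))
    expect_gte(mean_dose(h), d98)
    # monotone non-increasing in the volume fraction
    xs <- sort(runif(10, 1, 100))
    vals <- vapply(xs, function(x) dose_at_volume(h, x), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
    ms <- make_dose(sample(doses))
    hs <- dvh(ms$dose, ms$mask)
    expect_equal(dose_at_volume(hs, 37), dose_at_volume(h, 37))
  }
})

test_that("delta_dx implements evaluated-minus-reference over D_pres", {
  a <- list(d2 = 61, d95 = 57, d98 = 55, dmean = 60)
  b <- list(d2 = 60, d95 = 57.6, d98 = 55, dmean = 59.4)
  dd <- delta_dx(a, b, d_pres = 60)
  expect_equal(dd[["d2"]], 100 * 1 / 60)          # +1.667 %
  expect_equal(round(dd[["d2"]], 3), 1.667)
  expect_equal(dd[["d95"]], -1)
  expect_equal(dd[["d98"]], 0)
  expect_equal(delta_dx(b, a, 60), -dd)           # antisymmetry
  expect_equal(unname(delta_dx(a, a, 60)), rep(0, 4))
  expect_error(delta_dx(a, b, 0), "d_pres")
})

test_that("dvh_curve exports a descending cumulative curve", {
  m <- make_dose(c(3, 1, 2))
  cv <- dvh_curve(dvh(m$dose, m$mask))
  expect_equal(cv$dose_gy, c(3, 2, 1))
  expect_equal(cv$volume_fraction, c(1, 2, 3) / 3)
})
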