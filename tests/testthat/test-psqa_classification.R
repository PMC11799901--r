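test_that("tolerances are applied inclusively per metric kind", {
  tol <- tolerance_set()
  expect_equal(apply_tolerance(0.5, "point_percent", tol), "accept")
  expect_equal(apply_tolerance(-0.5, "point_percent", tol), "accept")
  expect_equal(apply_tolerance(1.0, "point_percent", tol), "accept")
  expect_equal(apply_tolerance(-1.0, "point_percent", tol), "accept")
  expect_equal(apply_tolerance(1.01, "point_percent", tol), "reject")
  expect_equal(apply_tolerance(92, "gamma_rate", tol), "accept")
  expect_equal(apply_tolerance(90, "gamma_rate", tol), "accept")
  expect_equal(apply_tolerance(89.9, "gamma_rate", tol), "reject")
})

test_that("tightening tolerances never converts a reject into an accept", {
  set.seed(4)
  vals <- runif(200, -3, 3)
  loose <- apply_tolerance(vals, "point_percent", tolerance_set(1.5))
  tight <- apply_tolerance(vals, "point_percent", tolerance_set(0.8))
  expect_true(all(!(loose == "reject" & tight == "accept")))
  rates <- runif(200, 70, 100)
  loose_g <- apply_tolerance(rates, "gamma_rate", tolerance_set(, 85))
  tight_g <- apply_tolerance(rates, "gamma_rate", tolerance_set(, 95))
  expect_true(all(!(loose_g == "reject" & tight_g == "accept")))
})

vd <- function(ids, decisions) data.frame(patient_id = ids,
                                          decision = decisions)

test_that("confusion counts follow the accept-is-positive convention", {
  all_acc <- vd(1:10, rep("accept", 10))
  cc <- confusion(all_acc, all_acc)
  expect_equal(c(cc$tp, cc$fn, cc$fp, cc$tn), c(10, 0, 0, 0))
  # CT accepts all, QA rejects one -> that patient is a false negative
  qa <- vd(1:10, c(rep("accept", 9), "reject"))
  cc2 <- confusion(all_acc, qa)
  expect_equal(c(cc2$tp, cc2$fn, cc2$fp, cc2$tn), c(9, 1, 0, 0))
  # CT rejects exactly one, QA accepts everyone -> one false positive
  ref <- vd(1:10, c("reject", rep("accept", 9)))
  cc3 <- confusion(ref, all_acc)
  expect_equal(c(cc3$tp, cc3$fn, cc3$fp, cc3$tn), c(9, 0, 1, 0))
})

test_that("confusion matches brute-force enumeration on random verdicts", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    ref <- vd(seq_len(n), sample(c("accept", "reject"), n, replace = TRUE))
    qa <- vd(sample(seq_len(n)), sample(c("accept", "reject"), n,
                                        replace = TRUE))
    cc <- confusion(ref, qa)
    q <- qa$decision[match(ref$patient_id, qa$patient_id)]
    expect_equal(cc$tp, sum(q == "accept" & ref$decision == "accept"))
    expect_equal(cc$fn, sum(q == "reject" & ref$decision == "accept"))
    expect_equal(cc$fp, sum(q == "accept" & ref$decision == "reject"))
    expect_equal(cc$tn, sum(q == "reject" & ref$decision == "reject"))
    expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, n)
  }
})

test_that("patient-set mismatches are rejected unless explicitly excluded", {
  ref <- vd(1:5, rep("accept", 5))
  qa <- vd(1:4, rep("accept", 4))
  expect_error(confusion(ref, qa), "same patients")
  cc <- confusion(ref, qa, excluded = 5L)     # auto-rejected artifact case
  expect_equal(cc$n, 4)
  expect_equal(cc$tp, 4)
})

test_that("sensitivity and specificity are exact ratios, NA when undefined", {
  cc <- structure(list(tp = 10, fn = 0, fp = 0, tn = 0, n = 10,
                       excluded = integer(0)), class = "confusion_counts")
  expect_equal(sensitivity(cc), 1)
  cc$tp <- 9; cc$fn <- 1
  expect_equal(sensitivity(cc), 0.9)
  cc$tp <- 0; cc$fn <- 0; cc$tn <- 3; cc$fp <- 1
  expect_true(is.na(sensitivity(cc)))         # undefined, never 0
  expect_equal(specificity(cc), 0.75)
  cc$tn <- 0; cc$fp <- 0
  expect_true(is.na(specificity(cc)))
})

test_that("verdict tables are deterministic and order-independent", {
  reports <- data.frame(patient_id = c(2, 1), reference = "CT",
                        me_ptv_pct = c(0.4, -1.2),
                        delta_d2_pct = c(1.5, 0.1),
                        delta_d95_pct = 0, delta_d98_pct = 0,
                        delta_dmean_pct = 0,
                        gamma_pass_pct = c(95, 85))
  v <- verdict_table(reports)
  expect_equal(v$decision[v$patient_id == 1 & v$metric == "me_ptv"], "reject")
  expect_equal(v$decision[v$patient_id == 2 & v$metric == "d2"], "reject")
  expect_equal(v$decision[v$patient_id == 2 & v$metric == "gamma"], "accept")
  v2 <- verdict_table(reports[2:1, ])
  expect_equal(v[order(v$patient_id, v$metric), "decision"],
               v2[order(v2$patient_id, v2$metric), "decision"])
})
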