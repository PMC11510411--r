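one_clone <- function(id = 1, kout = 0.016, Imax = 0.97, IC50 = 0.07,
                      PASI0 = 14.4, pk = typical_pk()) {
  data.frame(id = id, ka = pk$ka, F = pk$F, CL = pk$CL, Q = pk$Q, V2 = pk$V2,
             V3 = pk$V3, kout = kout, Imax = Imax, IC50 = IC50, PASI0 = PASI0,
             eta_kout = 0, eta_rv = 0, clone = 1)
}

test_that("probability of target attainment is exact counting", {
  pr <- probability_target(c(rep(0.5, 90), rep(3, 10)), target = 1)
  expect_identical(pr$npasi, 90L)
  expect_identical(pr$probability, 90)
  # inclusive boundary: values exactly at the target count
  expect_identical(probability_target(rep(1.0, 100))$probability, 100)
  expect_error(probability_target(numeric(0)), "no PASI")
  # brute-force counting oracle on random vectors
  set.seed(2)
  for (k in 1:20) {
    v <- runif(100, 0, 5)
    n_brute <- 0L
    for (x in v) if (x <= 1) n_brute <- n_brute + 1L
    expect_identical(probability_target(v)$probability, 100 * n_brute / 100)
  }
})

test_that("regimen selection prefers the lowest dose intensity above threshold", {
  probs <- data.frame(dose = c(45, 45, 90, 45), interval = c(12, 16, 8, 20),
                      probability = c(95, 92, 99, 40))
  d <- select_regimen(probs, current = regimen(90, 12))
  expect_identical(format(d$selected), "45 mg q16w") # 2.8125 mg/wk, minimal qualifier
  expect_identical(d$classification, "optimize")
  # empty qualifying set -> failure with no selection
  probs$probability <- c(10, 20, 80, 5)
  d2 <- select_regimen(probs, current = regimen(90, 12))
  expect_identical(d2$classification, "failure")
  expect_null(d2$selected)
  # higher intensity than current -> intensify; same regimen -> maintain
  probs3 <- data.frame(dose = 90, interval = 8, probability = 95)
  expect_identical(select_regimen(probs3, regimen(90, 12))$classification,
                   "intensify")
  probs4 <- data.frame(dose = 90, interval = 12, probability = 95)
  expect_identical(select_regimen(probs4, regimen(90, 12))$classification,
                   "maintain")
  # dose-intensity tie broken toward the longer interval
  probs5 <- data.frame(dose = c(45, 90), interval = c(8, 16),
                       probability = c(95, 95))
  expect_identical(format(select_regimen(probs5, regimen(90, 12))$selected),
                   "90 mg q16w")
})

test_that("switching to the same regimen equals uninterrupted dosing", {
  cl <- one_clone()
  r <- regimen(90, 12)
  sw <- simulate_cycles(cl, r, r)
  un <- simulate_cycles(cl, r, regimen(90, 12)) # same construction, 10 cycles
  expect_equal(sw$pasi_c10, un$pasi_c10, tolerance = 1e-9)
  # and equals a direct 10-cycle simulation evaluated at the same trough
  doses10 <- regimen_doses(regimen(90, 12, n_cycles = 10))
  pd <- pd_params(0.016, 0.97, 0.07, 14.4)
  ind <- typical_pk()
  direct <- pd_trajectory(pd, function(t) pk_concentration(ind, doses10, t),
                          10 * 84, h = 0.5)
  expect_equal(sw$pasi_c10, direct, tolerance = 1e-9)
})

test_that("washout after cycle 5 lets PASI relax back toward baseline", {
  cl <- rbind(one_clone(kout = 0.016), one_clone(kout = 0.03))
  cl$clone <- 1:2
  sim <- simulate_cycles(cl, regimen(90, 12), regimen(0, 12))
  expect_true(all(sim$pasi_c10 > sim$pasi_c5))
  expect_true(all(sim$ctrough_c10 < sim$ctrough_c5))
})

test_that("more intensive regimens dominate: higher trough, lower PASI", {
  cl <- one_clone()
  hi <- simulate_cycles(cl, regimen(90, 12), regimen(90, 8))
  lo <- simulate_cycles(cl, regimen(90, 12), regimen(45, 20))
  expect_gt(hi$ctrough_c10, lo$ctrough_c10)
  expect_lt(hi$pasi_c10, lo$pasi_c10)
})

test_that("cohort decisions partition into the four classes with full accounting", {
  coh <- generate_cohort(cohort_config(n = 8), seed = 31)
  model <- pop_model()
  pk <- pk_individuals_from_truth(coh)
  cl <- clone_cohort(coh, model, pk, n_draws = 30, burn = 200, thin = 3,
                     master_seed = 5)
  res <- mipd_decide(coh, cl)
  d <- res$decisions
  expect_identical(nrow(d), 8L)
  expect_true(all(d$classification %in% c("maintain", "optimize", "intensify",
                                          "failure")))
  # failure iff no candidate reaches the threshold
  expect_identical(d$classification == "failure", d$best_prob10 < 90)
  expect_true(all(is.na(d$selected) == (d$classification == "failure")))
  # probabilities cover the full grid and live in [0, 100]
  expect_identical(nrow(res$probabilities), 64L)
  expect_true(all(res$probabilities$probability >= 0 &
                    res$probabilities$probability <= 100))
})

test_that("exposure-response table pairs troughs with PASI and orders regimens", {
  coh <- generate_cohort(cohort_config(n = 4), seed = 32)
  model <- pop_model()
  pk <- pk_individuals_from_truth(coh)
  cl <- clone_cohort(coh, model, pk, n_draws = 20, burn = 150, thin = 3,
                     master_seed = 6)
  res <- mipd_decide(coh, cl)
  er <- exposure_response_table(res$records)
  expect_identical(nrow(er$summary), 8L)
  # dominance pairs on shared clones: fraction at target is non-decreasing in
  # dose at fixed interval
  s <- er$summary
  for (iv in unique(s$interval)) {
    ss <- s[s$interval == iv, ]
    ss <- ss[order(ss$dose), ]
    expect_true(all(diff(ss$frac_at_target) >= 0))
    expect_true(all(diff(ss$median_ctrough) > 0))
  }
  # zero-dose pseudo-regimen: trough 0 and PASI back at baseline
  wash <- simulate_cycles(cl[cl$id == cl$id[1], ][1, ], regimen(0, 12),
                          regimen(0, 12))
  expect_identical(wash$ctrough_c10, 0)
  expect_equal(wash$pasi_c10, cl$PASI0[cl$id == cl$id[1]][1], tolerance = 1e-8)
})

test_that("annual dose counts and costs follow the induction-plus-maintenance rule", {
  # first year of 45 mg q16w: doses at weeks 0, 4, 20, 36 -> EUR 11,661.6
  fy <- annual_cost(regimen(45, 16), price = 2915.4, year = "first")
  expect_identical(fy$n_doses, 4L)
  expect_equal(fy$cost, 11661.6)
  # labelled q12w first year: weeks 0, 4, 16, 28, 40 -> five doses
  expect_identical(annual_cost(regimen(45, 12), year = "first")$n_doses, 5L)
  # maintenance years
  expect_identical(annual_cost(regimen(45, 12), year = "maintenance")$n_doses, 4L)
  expect_identical(annual_cost(regimen(45, 16), year = "maintenance")$n_doses, 3L)
  # moving q12w -> q16w saves exactly 25% of maintenance cost
  expect_equal(cost_saving(regimen(45, 12), regimen(45, 16)), 25)
  expect_equal(cost_saving(regimen(45, 16), regimen(45, 16)), 0)
  # scale invariance in price is structural: saving uses counts only
  expect_error(annual_cost(regimen(45, 16), price = 0), "positive")
})
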