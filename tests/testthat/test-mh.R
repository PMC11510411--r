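test_that("conjugate toy: sampled posterior matches the closed form", {
  set.seed(8)
  y <- rnorm(6, 0.7, 0.5)
  tg <- toy_target(y)
  cs <- mh_sample(tg, n_draws = 2000, burn = 500, thin = 5, seed = 123)
  draws <- cs$eta_kout
  mcse_mean <- tg$post_sd / sqrt(2000 / 5) # conservative ESS guess
  expect_lt(abs(mean(draws) - tg$post_mean), 3 * mcse_mean)
  expect_lt(abs(sd(draws) - tg$post_sd), 3 * tg$post_sd / sqrt(2 * 2000 / 5))
  rate <- attr(cs, "accept_rate")
  expect_gt(rate, 0.05); expect_lt(rate, 0.8)
})

test_that("with no data the conditional distribution reproduces the prior", {
  model <- pop_model()
  p <- make_patient(1, 92, 14.4, regimen_doses(regimen(90, 12, 5)))
  tg <- conditional_target(p, model, typical_pk())
  cs <- mh_sample(tg, n_draws = 2000, burn = 300, thin = 3, seed = 7)
  n_eff <- 2000 / 3
  # every sampled dimension matches its prior moments within 3 MC SEs
  for (dim in c("eta_kout", "eta_rv")) {
    sd0 <- if (dim == "eta_kout") model$omega_kout else model$sigma_pd
    expect_lt(abs(mean(cs[[dim]])), 3 * sd0 / sqrt(n_eff))
    expect_lt(abs(sd(cs[[dim]]) - sd0), 3 * sd0 / sqrt(2 * n_eff))
  }
  # clone rows are complete valid parameter vectors
  expect_true(all(cs$kout > 0) && all(cs$PASI0 > 0))
  expect_identical(nrow(cs), 2000L)
})

test_that("sampling is bitwise reproducible under a fixed seed", {
  model <- pop_model()
  coh <- generate_cohort(cohort_config(n = 2), seed = 9)
  pk <- pk_individuals_from_truth(coh)
  tg <- conditional_target(coh[[1]], model, pk[[1]])
  c1 <- mh_sample(tg, n_draws = 50, seed = 11)
  c2 <- mh_sample(tg, n_draws = 50, seed = 11)
  expect_identical(c1, c2)
  c3 <- mh_sample(tg, n_draws = 50, seed = 12)
  expect_false(identical(c1$eta_kout, c3$eta_kout))
})

test_that("proposal adaptation is monotone, capped, and frozen after burn-in", {
  expect_gt(adapt_proposal(rep(c(TRUE, FALSE), c(9, 1)), 1), 1)   # 90% accept
  expect_lt(adapt_proposal(rep(c(TRUE, FALSE), c(1, 19)), 1), 1)  # 5% accept
  s <- 1
  for (i in 1:200) s <- adapt_proposal(rep(TRUE, 50), s, init_scale = 1)
  expect_equal(s, 10) # cap at x10 of the initial scale
  for (i in 1:400) s <- adapt_proposal(rep(FALSE, 50), s, init_scale = 1)
  expect_equal(s, 1 / 10) # cap at /10
  # no burn-in means no adaptation: scale multiplier stays at 1
  cs <- mh_sample(toy_target(rnorm(4)), n_draws = 100, burn = 0, seed = 3)
  expect_equal(attr(cs, "scale"), 1)
})

test_that("one MH transition preserves an exact posterior sample (detailed balance)", {
  set.seed(15)
  y <- rnorm(5, 0.4, 0.5)
  tg <- toy_target(y)
  n <- 5000
  x <- rnorm(n, tg$post_mean, tg$post_sd) # exact posterior draws
  prop <- x + 0.4 * rnorm(n)
  lr <- vapply(seq_len(n), function(i) tg$log_post(prop[i]) - tg$log_post(x[i]),
               numeric(1))
  acc <- log(runif(n)) < lr
  x1 <- ifelse(acc, prop, x)
  expect_lt(abs(mean(x1) - tg$post_mean), 3 * tg$post_sd / sqrt(n))
  expect_lt(abs(sd(x1) - tg$post_sd), 3 * tg$post_sd / sqrt(2 * n))
})

test_that("conditional distribution concentrates as observation noise vanishes", {
  pk <- typical_pk()
  doses <- regimen_doses(regimen(90, 12, n_cycles = 8))
  tobs <- seq(28, 500, by = 28)
  true_pd <- pd_params(0.016 * exp(0.4), 0.97, 0.07, 14)
  lat <- pd_trajectory(true_pd, function(t) pk_concentration(pk, doses, t), tobs)
  sds <- vapply(c(0.86, 0.4, 0.15), function(sig) {
    set.seed(99)
    dv <- lat * exp(rnorm(length(lat), 0, sig))
    p <- make_patient(1, 92, 14, doses,
                      pd_obs = data.frame(time = tobs, dv = dv))
    model <- pop_model(sigma_pd = sig)
    cs <- mh_sample(conditional_target(p, model, pk), n_draws = 300,
                    burn = 400, thin = 4, seed = 5)
    sd(cs$eta_kout)
  }, numeric(1))
  expect_true(all(diff(sds) < 0)) # posterior SD shrinks monotonically
})

test_that("clone sets span the configured draw count across a cohort", {
  coh <- generate_cohort(cohort_config(n = 3), seed = 4)
  model <- pop_model()
  pk <- pk_individuals_from_truth(coh)
  cl <- clone_cohort(coh, model, pk, n_draws = 40, burn = 200, thin = 4,
                     master_seed = 2)
  expect_identical(nrow(cl), 120L)
  expect_identical(as.integer(table(cl$id)), rep(40L, 3))
  cl2 <- clone_cohort(coh, model, pk, n_draws = 40, burn = 200, thin = 4,
                      master_seed = 2)
  expect_identical(as.data.frame(cl), as.data.frame(cl2))
})
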