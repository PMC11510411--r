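make_pk_patient <- function(id, pop, weight = 92, eta = NULL,
                            reg = regimen(90, 12, n_cycles = 6),
                            t_obs, noise_sd = 0, seed = 1) {
  ind <- apply_covariates(pop, weight, eta)
  doses <- regimen_doses(reg)
  set.seed(seed)
  cl <- pk_concentration(ind, doses, t_obs)
  dv <- cl * (1 + rnorm(length(t_obs), 0, noise_sd))
  make_patient(id, weight, 14.4, doses,
               pk_obs = data.frame(time = t_obs, dv = dv, cens = 0L), reg = reg)
}

test_that("MAP individual PK: prior mode, self-consistency and recovery", {
  pop <- pk_population()
  # no observations -> covariate-typical individual, eta = 0
  p0 <- make_patient(1, 80, 14.4, regimen_doses(regimen(90, 12, 5)))
  m0 <- map_individual_pk(p0, pop)
  expect_identical(unname(m0$eta), rep(0, 5))
  expect_equal(m0$ind$CL, apply_covariates(pop, 80)$CL)
  # single observation at the typical prediction -> eta ~ 0
  p1 <- make_pk_patient(2, pop, t_obs = 340)
  m1 <- map_individual_pk(p1, pop)
  expect_lt(max(abs(m1$eta)), 1e-3)
  # dense noise-free data from CL = 1.5 x typical -> CL recovered within 5%
  p2 <- make_pk_patient(3, pop, eta = c(CL = log(1.5)), t_obs = seq(7, 500, 7))
  m2 <- map_individual_pk(p2, pop)
  expect_lt(abs(m2$ind$CL / (1.5 * apply_covariates(pop, 92)$CL) - 1), 0.05)
})

test_that("below-quantification PK observations are excluded and counted", {
  pop <- pk_population()
  p <- make_pk_patient(4, pop, t_obs = c(170, 340))
  p$pk_obs$cens <- c(1L, 0L)
  p$pk_obs$dv[1] <- 0.3
  m <- map_individual_pk(p, pop)
  expect_identical(m$n_blq, 1L)
  expect_identical(m$n_obs, 1L)
})

sim_fit_cohort <- function(n, seed, model = pop_model(), pd_to = 364) {
  cc <- cohort_config(n = n, model = model, pd_times = seq(14, pd_to, by = 14))
  coh <- generate_cohort(cc, seed = seed)
  list(coh = coh, pk = pk_individuals_from_truth(coh))
}

test_that("no-heterogeneity limit: omega_kout estimate shrinks toward zero", {
  s <- sim_fit_cohort(20, seed = 21,
                      model = pop_model(omega_kout = 0, sigma_pd = 0.3),
                      pd_to = 546)
  fit <- fit_population_pd(s$coh, s$pk, n_starts = 1)
  expect_lt(fit$estimates$omega_kout, 0.1)
})

test_that("residual-error scale is recovered and tracks the simulated noise", {
  s1 <- sim_fit_cohort(15, seed = 22, model = pop_model(sigma_pd = 0.43))
  f1 <- fit_population_pd(s1$coh, s1$pk, n_starts = 1)
  s2 <- sim_fit_cohort(15, seed = 22, model = pop_model(sigma_pd = 0.86))
  f2 <- fit_population_pd(s2$coh, s2$pk, n_starts = 1)
  ratio <- f2$estimates$sigma_pd / f1$estimates$sigma_pd
  expect_lt(abs(ratio - 2), 0.4) # doubling the noise doubles sigma within 20%
})

test_that("objective function: optimality, additivity and permutation invariance", {
  s <- sim_fit_cohort(8, seed = 23)
  fit <- fit_population_pd(s$coh, s$pk, n_starts = 4)
  e <- fit$estimates
  m_hat <- pop_model(kout_pop = e$kout_pop, Imax_pop = e$Imax_pop,
                     IC50 = e$IC50, omega_kout = e$omega_kout,
                     sigma_pd = e$sigma_pd)
  o_hat <- objective_value(m_hat, s$coh, s$pk)
  # relaxing from any constrained (perturbed) model can only lower the optimum
  for (m_pert in list(pop_model(kout_pop = 2 * e$kout_pop, Imax_pop = e$Imax_pop,
                                omega_kout = e$omega_kout, sigma_pd = e$sigma_pd),
                      pop_model(kout_pop = e$kout_pop, Imax_pop = 0.8,
                                omega_kout = e$omega_kout, sigma_pd = e$sigma_pd))) {
    expect_gte(objective_value(m_pert, s$coh, s$pk) - o_hat, 0)
  }
  # duplicating every subject doubles the objective
  dup <- as_cohort(c(s$coh, lapply(s$coh, function(p) { p$id <- p$id + 100; p })))
  pk2 <- c(s$pk, setNames(s$pk, as.character(101:108)))
  expect_equal(objective_value(m_hat, dup, pk2), 2 * o_hat, tolerance = 1e-6)
  # permuting subjects leaves the objective unchanged
  perm <- as_cohort(s$coh[c(5, 3, 8, 1, 2, 7, 6, 4)])
  expect_lt(abs(objective_value(m_hat, perm, s$pk) - o_hat), 1e-9)
})

test_that("marginal likelihood matches independent adaptive quadrature on one subject", {
  s <- sim_fit_cohort(1, seed = 30)
  m <- pop_model()
  o_lap <- objective_value(m, s$coh, s$pk, estimate_baseline = FALSE)
  # independent route: the same joint density, but the random-effect integral
  # done by brute-force adaptive quadrature (integrate) on the same joint
  p <- s$coh[[1]]
  ind <- s$pk[[1]]
  obs <- p$pd_obs
  conc <- function(t) pk_concentration(ind, p$doses, t)
  joint <- function(eta) {
    vapply(eta, function(e) {
      pd <- pd_params(m$kout_pop * exp(e), m$Imax_pop, m$IC50, p$pasi0)
      pred <- pd_trajectory(pd, conc, obs$time, method = "quadrature", h = 0.5)
      ll <- sum(dnorm(log(pmax(obs$dv, 0.1)), log(pred), m$sigma_pd, log = TRUE) -
                  log(pmax(obs$dv, 0.1)))
      exp(ll + dnorm(e, 0, m$omega_kout, log = TRUE))
    }, numeric(1))
  }
  marg <- integrate(joint, -6 * m$omega_kout, 6 * m$omega_kout,
                    rel.tol = 1e-10)$value
  o_quad <- -2 * log(marg)
  expect_lt(abs(o_lap - o_quad), 1e-3 * abs(o_quad))
  # and the ODE-solver route stays consistent at its own tolerance
  pd0 <- pd_params(m$kout_pop, m$Imax_pop, m$IC50, p$pasi0)
  expect_equal(pd_trajectory(pd0, conc, obs$time, method = "quadrature", h = 0.1),
               pd_trajectory(pd0, conc, obs$time, method = "ode"),
               tolerance = 1e-3)
})

test_that("baseline random effect is marginalized exactly (2-D quadrature oracle)", {
  s <- sim_fit_cohort(1, seed = 35)
  m <- pop_model()
  o_pkg <- objective_value(m, s$coh, s$pk, estimate_baseline = TRUE)
  sub <- utkmipd:::pd_fit_data(s$coh, s$pk)[[1]]
  Ig <- m$Imax_pop * sub$Cgrid / (m$IC50 + sub$Cgrid)
  joint <- function(e1, e2) exp(-utkmipd:::subject_joint_nll(
    c(e1, e2), sub, m$kout_pop, m$omega_kout, m$sigma_pd, Ig, TRUE))
  inner <- function(e1) vapply(e1, function(a)
    integrate(function(b) vapply(b, function(x) joint(a, x), numeric(1)),
              -6 * m$sigma_pd, 6 * m$sigma_pd, rel.tol = 1e-9)$value,
    numeric(1))
  marg <- integrate(inner, -6 * m$omega_kout, 6 * m$omega_kout,
                    rel.tol = 1e-8)$value
  expect_lt(abs(o_pkg - (-2 * log(marg))), 1e-3 * abs(o_pkg))
})

test_that("uncertainty shrinks with cohort size", {
  s_small <- sim_fit_cohort(10, seed = 31)
  s_large <- sim_fit_cohort(40, seed = 31)
  f_small <- fit_population_pd(s_small$coh, s_small$pk, n_starts = 1)
  f_large <- fit_population_pd(s_large$coh, s_large$pk, n_starts = 1)
  expect_lt(f_large$rse[["kout_pop"]], f_small$rse[["kout_pop"]])
})

test_that("degenerate cohorts are rejected with an informative error", {
  coh <- as_cohort(list(make_patient(1, 90, 14, regimen_doses(regimen(90, 12, 3)))))
  expect_error(fit_population_pd(coh, list(`1` = typical_pk())),
               "no usable PASI")
})
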