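# ---- population PD estimation (marginal maximum likelihood) ----
#
# Random effects per subject: eta_kout ~ N(0, omega^2) on log kout and, under
# the B2 baseline method, eta_RV ~ N(0, sigma^2) with
# PASI_i = PASI_i0 * exp(eta_RV). The PD residual is multiplicative
# log-normal with log-scale SD sigma, which ties the baseline variance to the
# residual variance during estimation.

LOG2PI <- log(2 * pi)

# Per-subject precomputation: observation times/values, uniform time grid and
# the (fixed) individual concentration on it. `pk_ind` is a list of
# pk_individual keyed by as.character(id), or a list of map results.
pd_fit_data <- function(cohort, pk_ind, h = 0.5, pasi_floor = 0.1) {
  n_floored <- 0L
  subs <- lapply(cohort, function(p) {
    obs <- p$pd_obs[p$pd_obs$time > 0 & is.finite(p$pd_obs$dv), , drop = FALSE]
    if (nrow(obs) == 0) return(NULL)
    ind <- pk_ind[[as.character(p$id)]]
    if (is.list(ind) && !inherits(ind, "pk_individual")) ind <- ind$ind
    if (is.null(ind)) stop("no PK parameters for subject ", p$id, call. = FALSE)
    y <- obs$dv
    n_floored <<- n_floored + sum(y < pasi_floor)
    y <- pmax(y, pasi_floor)
    grid <- uniform_grid(max(obs$time), h)
    list(id = p$id, tobs = obs$time, y = y, logy = log(y), pasi0 = p$pasi0,
         grid = grid, hg = grid[2] - grid[1],
         interp = grid_interp_setup(grid, obs$time),
         Cgrid = pk_concentration(ind, p$doses, grid))
  })
  subs <- Filter(Negate(is.null), subs)
  if (length(subs) == 0) stop("cohort has no usable PASI observations", call. = FALSE)
  if (n_floored > 0) {
    message(sprintf("pd fit: %d PASI observation(s) below %g floored", n_floored, pasi_floor))
  }
  subs
}

# Negative joint log-density of one subject's PASI data and random effects.
# eta = c(eta_kout, eta_rv); Igrid is inhibition on the subject's grid. Used
# by the conditional sampler and by the exact-marginal derivation below.
subject_joint_nll <- function(eta, sub, kout_pop, omega, sigma, Igrid,
                              estimate_baseline) {
  kout_i <- kout_pop * exp(eta[1])
  p0_i <- if (estimate_baseline) sub$pasi0 * exp(eta[2]) else sub$pasi0
  pasi <- pasi_on_grid(kout_i, p0_i, Igrid, sub$hg)
  pred <- grid_interp(pasi, sub$interp)
  if (any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
  nll <- sum(log(sigma) + 0.5 * LOG2PI + sub$logy +
               0.5 * ((sub$logy - log(pred)) / sigma)^2) +
    0.5 * LOG2PI + log(omega) + eta[1]^2 / (2 * omega^2)
  if (estimate_baseline) {
    nll <- nll + 0.5 * LOG2PI + log(sigma) + eta[2]^2 / (2 * sigma^2)
  }
  nll
}

# -log marginal likelihood of one subject.
#
# Under the B2 method the baseline deviation eta_RV enters the log-scale
# observation model *linearly* (log y_j = log pred_j(eta_kout) + eta_RV +
# eps_j) with prior variance equal to the residual variance, so it is
# integrated out exactly: log y | eta_kout is multivariate normal with
# covariance sigma^2 (I + 11') whose determinant is sigma^(2n) (n+1). The
# remaining 1-D integral over eta_kout is done by deterministic trapezoid
# quadrature on nodes placed around the located mode plus a prior-scale
# grid. A pure Laplace expansion is deliberately avoided here: the profile
# can be bimodal (fast-remission/high-baseline vs slow-remission/
# low-baseline) and develops fold points where its curvature vanishes, at
# which 0.5*log(H) diverges and drags the outer optimizer into spurious
# spikes.
subject_marginal_nll <- function(sub, kout_pop, Imax, IC50, omega, sigma,
                                 estimate_baseline, start = NULL) {
  Igrid <- Imax * sub$Cgrid / (IC50 + sub$Cgrid)
  n <- length(sub$logy)
  logpred <- function(e1) {
    pasi <- pasi_on_grid(kout_pop * exp(e1), sub$pasi0, Igrid, sub$hg)
    pred <- grid_interp(pasi, sub$interp)
    if (any(!is.finite(pred)) || any(pred <= 0)) return(NULL)
    log(pred)
  }
  h1 <- function(e1) {
    lp <- logpred(e1)
    if (is.null(lp)) return(1e10)
    r <- sub$logy - lp
    nll_y <- if (estimate_baseline) {
      n / 2 * LOG2PI + n * log(sigma) + 0.5 * log1p(n) +
        (sum(r^2) - sum(r)^2 / (n + 1)) / (2 * sigma^2) + sum(sub$logy)
    } else {
      n / 2 * LOG2PI + n * log(sigma) + sum(r^2) / (2 * sigma^2) + sum(sub$logy)
    }
    nll_y + 0.5 * LOG2PI + log(omega) + e1^2 / (2 * omega^2)
  }
  scan <- seq(-3, 3, by = 1)
  if (!is.null(start)) scan <- sort(c(start[1], scan))
  vals <- vapply(scan, h1, numeric(1))
  opt <- stats::nlminb(scan[which.min(vals)], h1, lower = -8, upper = 8)
  if (!is.finite(opt$objective) || opt$objective >= 1e10) {
    stop("non-finite likelihood for subject ", sub$id, call. = FALSE)
  }
  mode <- opt$par
  # local curvature (f0 re-evaluated: the optimizer's reported objective can
  # disagree with h1(par) at round-off level, amplified by 1/step^2)
  step <- 1e-3
  f0 <- h1(mode)
  H <- (h1(mode + step) - 2 * f0 + h1(mode - step)) / step^2
  sd_c <- if (is.finite(H) && H > 0) min(1 / sqrt(H), 2 * omega) else 2 * omega
  # quadrature nodes: fine around the mode, coarse over the prior scale
  # (catches secondary modes the polish did not land on)
  nodes <- sort(unique(c(mode + seq(-4, 4, by = 0.5) * sd_c,
                         seq(-4, 4, by = 0.8) * omega,
                         mode)))
  nodes <- nodes[nodes >= -8 & nodes <= 8]
  hv <- vapply(nodes, h1, numeric(1))
  hv[hv >= 1e10] <- Inf
  m0 <- min(hv, f0)
  w <- diff(nodes)
  g <- exp(-(hv - m0))
  integral <- sum(w * (g[-1] + g[-length(g)]) / 2)
  eta2 <- if (estimate_baseline) {
    lp <- logpred(mode)
    sum(sub$logy - lp) / (n + 1) # conditional posterior mean of eta_RV
  } else 0
  list(nll = m0 - log(integral), eta = c(mode, eta2))
}

transform_pd <- function(kout, Imax, omega, sigma) {
  c(lkout = log(kout), zImax = stats::qlogis(Imax),
    lomega = log(omega), lsigma = log(sigma))
}

untransform_pd <- function(par) {
  list(kout_pop = exp(par[[1]]), Imax_pop = stats::plogis(par[[2]]),
       omega_kout = exp(par[[3]]), sigma_pd = exp(par[[4]]))
}

# -2 log marginal likelihood over the cohort. Every evaluation locates the
# inner modes from the same fixed start grid, so the value depends only on
# `par` (no history effects that would corrupt finite-difference gradients).
pd_m2ll <- function(par, subs, IC50, estimate_baseline, eta_out = NULL) {
  th <- untransform_pd(par)
  total <- 0
  for (i in seq_along(subs)) {
    res <- subject_marginal_nll(subs[[i]], th$kout_pop, th$Imax_pop, IC50,
                               th$omega_kout, th$sigma_pd, estimate_baseline,
                               start = NULL)
    if (!is.null(eta_out)) eta_out$eta[i, seq_along(res$eta)] <- res$eta
    total <- total + res$nll
  }
  2 * total
}

#' Fit the population PD model by marginal maximum likelihood
#'
#' Estimates the PD fixed effects (`kout_pop`, `Imax_pop`), the IIV SD
#' `omega_kout` and the residual log-SD `sigma_pd` with `IC50` held fixed,
#' marginalizing the per-subject random effects: the B2 baseline deviation
#' `eta_RV` exactly (it enters the log-scale model linearly) and `eta_kout`
#' by deterministic adaptive 1-D quadrature. Individual PK
#' parameters are fixed beforehand (sequential PK -> PD estimation). A
#' bounded quasi-Newton optimizer runs from `n_starts` jittered initial
#' values, the distinct optima get a kink-tolerant Nelder-Mead polish, and
#' the best optimum is kept.
#'
#' @param cohort a `utk_cohort`; every subject needs a baseline PASI and at
#'   least one post-baseline PASI observation.
#' @param pk_ind named list of [pk_individual()] (or [map_individual_pk()]
#'   results) keyed by subject id.
#' @param init named list of starting values
#'   (`kout`, `Imax`, `omega_kout`, `sigma_pd`).
#' @param IC50 fixed half-maximal concentration (mg/L), excluded from
#'   estimation.
#' @param estimate_baseline use the B2 baseline method (`eta_RV` sampled with
#'   variance tied to `sigma_pd^2`); if `FALSE` the observed baseline is
#'   taken as exact and only `eta_kout` is marginalized.
#' @param pasi_floor lower floor applied to PASI observations before taking
#'   logs (PASI 0 is observable; the log-normal error is not defined at 0).
#' @param n_starts number of optimizer starts (first = `init`, rest jittered).
#' @param seed seed for start jitter.
#' @param h time-grid step (days) of the PD solver.
#' @return object of class `pd_fit`: estimates, RSE (%), `objective`
#'   (-2 log marginal likelihood), per-subject empirical-Bayes modes `eb`,
#'   and optimizer diagnostics.
#' @export
fit_population_pd <- function(cohort, pk_ind,
                              init = list(kout = 0.03, Imax = 0.9,
                                          omega_kout = 0.4, sigma_pd = 0.6),
                              IC50 = 0.07, estimate_baseline = TRUE,
                              pasi_floor = 0.1, n_starts = 5, seed = 20240101,
                              h = 0.5) {
  subs <- pd_fit_data(cohort, pk_ind, h = h, pasi_floor = pasi_floor)
  lower <- c(log(1e-5), -12, log(1e-4), log(1e-3))
  upper <- c(log(2), 12, log(5), log(5))

  p0 <- transform_pd(init$kout, init$Imax, init$omega_kout, init$sigma_pd)
  set.seed(seed)
  starts <- c(list(p0), lapply(seq_len(max(0, n_starts - 1)), function(k) {
    pmin(pmax(p0 + stats::rnorm(4, 0, 0.4), lower + 0.01), upper - 0.01)
  }))

  best <- NULL
  trace <- data.frame(start = seq_along(starts), objective = NA_real_,
                      convergence = NA_integer_)
  obj <- function(p) pd_m2ll(p, subs, IC50, estimate_baseline)
  qns <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    qn <- try(stats::nlminb(starts[[k]], obj, lower = lower, upper = upper,
                            control = list(rel.tol = 1e-8)), silent = TRUE)
    if (inherits(qn, "try-error")) next
    qns[[k]] <- qn
    trace$objective[k] <- qn$objective
    trace$convergence[k] <- qn$convergence
  }
  qns <- Filter(Negate(is.null), qns)
  if (length(qns) == 0) {
    stop("population PD estimation failed from every start", call. = FALSE)
  }
  # the marginal surface has derivative kinks where an inner mode switches
  # basins, which can stall the quasi-Newton pass; polish the distinct optima
  # (up to 3, best first) with a kink-tolerant simplex search
  qns <- qns[order(vapply(qns, `[[`, numeric(1), "objective"))]
  keys <- vapply(qns, function(q) paste(signif(q$par, 4), collapse = ","),
                 character(1))
  qns <- qns[!duplicated(keys)]
  best <- NULL
  for (q in qns[seq_len(min(3, length(qns)))]) {
    nm <- stats::optim(q$par, function(p) {
      if (any(p < lower) || any(p > upper)) return(1e12)
      obj(p)
    }, method = "Nelder-Mead", control = list(maxit = 300, reltol = 1e-10))
    cand <- if (nm$value < q$objective) {
      list(par = nm$par, objective = nm$value, convergence = nm$convergence)
    } else {
      list(par = q$par, objective = q$objective, convergence = q$convergence)
    }
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }

  est <- untransform_pd(best$par)
  est$IC50 <- IC50
  # re-evaluate at the optimum: optimizers can report an objective that
  # disagrees with obj(par) at round-off level, and objective_value() must
  # reproduce this number exactly
  objective <- obj(best$par)

  # observed-information RSEs on the natural scale (delta method)
  rse <- c(kout_pop = NA_real_, Imax_pop = NA_real_, omega_kout = NA_real_,
           sigma_pd = NA_real_)
  covm <- try({
    # wide finite-difference step: the surface is smooth at this scale while
    # sub-1e-3 steps only sample inner-optimizer noise
    Hh <- stats::optimHess(best$par, function(p)
      pd_m2ll(p, subs, IC50, estimate_baseline) / 2,
      control = list(ndeps = rep(0.02, 4), parscale = rep(1, 4)))
    solve(Hh)
  }, silent = TRUE)
  if (!inherits(covm, "try-error") && all(is.finite(diag(covm))) &&
      all(diag(covm) > 0)) {
    sds <- sqrt(diag(covm))
    rse["kout_pop"] <- 100 * sds[1]
    rse["Imax_pop"] <- 100 * sds[2] * est$Imax_pop * (1 - est$Imax_pop) / est$Imax_pop
    rse["omega_kout"] <- 100 * sds[3]
    rse["sigma_pd"] <- 100 * sds[4]
  }

  # per-subject empirical-Bayes modes at the optimum
  modes <- new.env()
  modes$eta <- matrix(0, length(subs), 2)
  invisible(pd_m2ll(best$par, subs, IC50, estimate_baseline, eta_out = modes))
  eb <- data.frame(
    id = vapply(subs, function(s) s$id, numeric(1)),
    eta_kout = modes$eta[, 1],
    eta_rv = if (estimate_baseline) modes$eta[, 2] else 0
  )
  eb$kout_i <- est$kout_pop * exp(eb$eta_kout)
  eb$pasi0_i <- vapply(subs, function(s) s$pasi0, numeric(1)) * exp(eb$eta_rv)

  structure(list(estimates = est, rse = rse, objective = objective,
                 eb = eb, convergence = best$convergence, starts = trace,
                 estimate_baseline = estimate_baseline, h = h,
                 pasi_floor = pasi_floor),
            class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  cat("Population PD fit (marginal ML)\n")
  e <- x$estimates
  cat(sprintf("  kout       %.5f /day  (RSE %.1f%%)\n", e$kout_pop, x$rse["kout_pop"]))
  cat(sprintf("  Imax       %.4f       (RSE %.1f%%)\n", e$Imax_pop, x$rse["Imax_pop"]))
  cat(sprintf("  IC50       %.3g mg/L  (fixed)\n", e$IC50))
  cat(sprintf("  omega_kout %.4f (log-SD; %.2f%%)  (RSE %.1f%%)\n",
              e$omega_kout, 100 * e$omega_kout, x$rse["omega_kout"]))
  cat(sprintf("  sigma_pd   %.4f (log-SD)  (RSE %.1f%%)\n", e$sigma_pd, x$rse["sigma_pd"]))
  cat(sprintf("  -2LL = %.3f over %d subjects\n", x$objective, nrow(x$eb)))
  invisible(x)
}

#' Objective-function value (-2 log marginal likelihood) of a PD model
#'
#' Deterministic given the model, data and approximation settings: the same
#' per-subject marginalization used in fitting (exact over the baseline
#' deviation, quadrature over `eta_kout`) is evaluated once at the supplied
#' parameters, so it reproduces `fit_population_pd()$objective` exactly when
#' given the fitted estimates.
#'
#' @param model a [pop_model()] (its PD components are evaluated).
#' @param cohort a `utk_cohort`.
#' @param pk_ind named list of individual PK parameter sets.
#' @param estimate_baseline,pasi_floor,h as in [fit_population_pd()].
#' @return the -2 log marginal likelihood.
#' @export
objective_value <- function(model, cohort, pk_ind, estimate_baseline = TRUE,
                            pasi_floor = 0.1, h = 0.5) {
  stopifnot(inherits(model, "pop_model"))
  subs <- pd_fit_data(cohort, pk_ind, h = h, pasi_floor = pasi_floor)
  par <- transform_pd(model$kout_pop, model$Imax_pop, model$omega_kout,
                      model$sigma_pd)
  pd_m2ll(par, subs, model$IC50, estimate_baseline)
}
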