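#' Empirical-Bayes (MAP) estimate of individual PK parameters
#'
#' Maximizes `log p(y_PK | eta) + log p(eta)` over the log-scale deviations
#' `eta` of the selected PK parameters, with a log-normal
#' (exponential-proportional) residual-error model for quantifiable
#' concentrations and independent normal priors
#' `eta_P ~ N(0, omega_P^2)`. Below-quantification observations are excluded
#' from the likelihood and counted. A patient with no quantifiable PK
#' observation gets the covariate-adjusted typical individual (`eta = 0`).
#'
#' @param patient a cohort element (list with `weight`, `doses`, `pk_obs`).
#' @param pop a [pk_population()]; its `omega` entries define the prior.
#' @param eta_dims PK parameters with estimated deviations (must have
#'   `omega > 0` in `pop`).
#' @return list with `ind` ([pk_individual()]), `eta` (named, full), `n_obs`,
#'   `n_blq`, `objective`, `convergence`.
#' @export
map_individual_pk <- function(patient, pop, eta_dims = c("CL", "V2")) {
  stopifnot(inherits(pop, "pk_population"))
  obs <- patient$pk_obs[patient$pk_obs$cens == 0L, , drop = FALSE]
  n_blq <- sum(patient$pk_obs$cens == 1L)
  eta_dims <- eta_dims[pop$omega[eta_dims] > 0]
  full0 <- c(ka = 0, CL = 0, Q = 0, V2 = 0, V3 = 0)

  if (nrow(obs) == 0 || length(eta_dims) == 0) {
    return(list(ind = apply_covariates(pop, patient$weight), eta = full0,
                n_obs = nrow(obs), n_blq = n_blq, objective = NA_real_,
                convergence = 0L))
  }

  sig <- pop$sigma_prop
  om <- pop$omega[eta_dims]
  logy <- log(obs$dv)
  nll <- function(eta) {
    ind <- apply_covariates(pop, patient$weight, stats::setNames(eta, eta_dims))
    f <- pk_concentration(ind, patient$doses, obs$time)
    if (any(f <= 0)) return(1e10)
    sum(0.5 * ((logy - log(f)) / sig)^2 + log(sig) + logy + 0.5 * LOG2PI) +
      sum(eta^2 / (2 * om^2))
  }
  fit <- stats::nlminb(numeric(length(eta_dims)), nll,
                       lower = rep(-6, length(eta_dims)),
                       upper = rep(6, length(eta_dims)))
  if (!is.finite(fit$objective)) {
    stop(sprintf("individual PK estimation failed for subject %s (last iterate: %s)",
                 patient$id, paste(signif(fit$par, 4), collapse = ", ")),
         call. = FALSE)
  }
  eta <- full0
  eta[eta_dims] <- fit$par
  list(ind = apply_covariates(pop, patient$weight, eta), eta = eta,
       n_obs = nrow(obs), n_blq = n_blq, objective = fit$objective,
       convergence = fit$convergence)
}

#' MAP PK estimates for a whole cohort
#'
#' @param cohort a `utk_cohort`.
#' @param pop a [pk_population()].
#' @param eta_dims see [map_individual_pk()].
#' @return named list (by subject id) of [map_individual_pk()] results.
#' @export
map_cohort_pk <- function(cohort, pop, eta_dims = c("CL", "V2")) {
  out <- lapply(cohort, map_individual_pk, pop = pop, eta_dims = eta_dims)
  names(out) <- vapply(cohort, function(p) as.character(p$id), character(1))
  out
}

#' Extract true individual PK parameter sets from a synthetic cohort
#'
#' Convenience for simulation studies where the PK side is treated as known.
#'
#' @param cohort a synthetic `utk_cohort` carrying hidden truths.
#' @return named list (by subject id) of [pk_individual()] objects.
#' @export
pk_individuals_from_truth <- function(cohort) {
  out <- lapply(cohort, function(p) {
    if (is.null(p$truth)) stop("cohort carries no hidden truths", call. = FALSE)
    p$truth$pk
  })
  names(out) <- vapply(cohort, function(p) as.character(p$id), character(1))
  out
}
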