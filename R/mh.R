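# ---- Metropolis-Hastings sampling of individual conditional distributions ----

#' Conditional-distribution target for one patient
#'
#' Builds the unnormalized log-density of `p(psi_i | y_i) proportional to
#' p(y_i | psi_i) p(psi_i)` over the sampled log-scale deviations. By default
#' the sampled dimensions are `eta_kout` (the declared PD random effect) and
#' `eta_RV` (the B2 baseline deviation, prior SD = `sigma_pd`), with the
#' individual PK parameters fixed at their empirical-Bayes values;
#' `sample_pk = TRUE` adds PK deviations (prior from `model$pk$omega`, PK
#' likelihood from the proportional error model) for full joint uncertainty.
#'
#' A patient with no observations yields a target equal to the prior.
#'
#' @param patient a cohort element.
#' @param model a [pop_model()].
#' @param pk_ind the patient's [pk_individual()] (empirical-Bayes or truth).
#' @param sample_pk also sample PK deviations for `CL` and `V2`.
#' @param pasi_floor floor for observed PASI before log transform.
#' @param h PD solver grid step (days).
#' @return object of class `conditional_target` with fields `dims`,
#'   `prior_sd`, `log_post(eta)`, `eb_mode()`, `make_clone(eta)`.
#' @export
conditional_target <- function(patient, model, pk_ind, sample_pk = FALSE,
                               pasi_floor = 0.1, h = 0.5) {
  stopifnot(inherits(model, "pop_model"), inherits(pk_ind, "pk_individual"))
  dims <- c("eta_kout", "eta_rv")
  prior_sd <- c(model$omega_kout, model$sigma_pd)
  pk_dims <- character(0)
  if (sample_pk) {
    pk_dims <- c("CL", "V2")
    dims <- c(dims, paste0("eta_", pk_dims))
    prior_sd <- c(prior_sd, unname(model$pk$omega[pk_dims]))
  }
  if (any(prior_sd <= 0)) stop("sampled dimensions need positive prior SDs", call. = FALSE)

  pdo <- patient$pd_obs[patient$pd_obs$time > 0 & is.finite(patient$pd_obs$dv), ,
                        drop = FALSE]
  has_pd <- nrow(pdo) > 0
  logy <- if (has_pd) log(pmax(pdo$dv, pasi_floor)) else numeric(0)
  grid <- if (has_pd) uniform_grid(max(pdo$time), h) else 0
  hg <- if (length(grid) > 1) grid[2] - grid[1] else h
  interp <- if (has_pd) grid_interp_setup(grid, pdo$time) else NULL
  Cgrid_fixed <- if (has_pd) pk_concentration(pk_ind, patient$doses, grid) else numeric(0)
  pko <- patient$pk_obs[patient$pk_obs$cens == 0L, , drop = FALSE]
  sig_pk <- model$pk$sigma_prop
  sigma <- model$sigma_pd

  # individual PK parameters implied by the PK block of eta
  ind_of <- function(eta) {
    if (!sample_pk) return(pk_ind)
    ind <- pk_ind
    for (j in seq_along(pk_dims)) {
      ind[[pk_dims[j]]] <- pk_ind[[pk_dims[j]]] * exp(eta[2 + j])
    }
    ind
  }

  loglik <- function(eta) {
    ll <- 0
    ind <- ind_of(eta)
    if (has_pd) {
      Cg <- if (sample_pk) pk_concentration(ind, patient$doses, grid) else Cgrid_fixed
      Ig <- model$Imax_pop * Cg / (model$IC50 + Cg)
      kout_i <- model$kout_pop * exp(eta[1])
      p0_i <- patient$pasi0 * exp(eta[2])
      pasi <- pasi_on_grid(kout_i, p0_i, Ig, hg)
      pred <- grid_interp(pasi, interp)
      if (any(!is.finite(pred)) || any(pred <= 0)) return(-Inf)
      ll <- ll - sum(log(sigma) + 0.5 * LOG2PI + logy +
                       0.5 * ((logy - log(pred)) / sigma)^2)
    }
    if (sample_pk && nrow(pko) > 0) {
      f <- pk_concentration(ind, patient$doses, pko$time)
      if (any(f <= 0)) return(-Inf)
      ll <- ll - sum(0.5 * ((log(pko$dv) - log(f)) / sig_pk)^2 + log(sig_pk) +
                       log(pko$dv) + 0.5 * LOG2PI)
    }
    ll
  }

  log_post <- function(eta) {
    lp <- loglik(eta)
    if (!is.finite(lp)) return(-Inf)
    lp - sum(eta^2 / (2 * prior_sd^2)) - sum(log(prior_sd)) -
      length(eta) / 2 * LOG2PI
  }

  eb_mode <- function() {
    if (!has_pd && !(sample_pk && nrow(pko) > 0)) return(numeric(length(dims)))
    opt <- stats::nlminb(numeric(length(dims)), function(e) -log_post(e),
                         lower = rep(-8, length(dims)), upper = rep(8, length(dims)))
    opt$par
  }

  make_clone <- function(eta) {
    ind <- ind_of(eta)
    data.frame(id = patient$id, ka = ind$ka, F = ind$F, CL = ind$CL, Q = ind$Q,
               V2 = ind$V2, V3 = ind$V3,
               kout = model$kout_pop * exp(eta[1]), Imax = model$Imax_pop,
               IC50 = model$IC50, PASI0 = patient$pasi0 * exp(eta[2]),
               eta_kout = eta[1], eta_rv = eta[2])
  }

  structure(list(dims = dims, prior_sd = prior_sd, log_post = log_post,
                 eb_mode = eb_mode, make_clone = make_clone,
                 patient_id = patient$id),
            class = "conditional_target")
}

#' Proposal-scale adaptation step
#'
#' Nudges the random-walk proposal scale toward a target acceptance rate;
#' used only during burn-in (the scale is frozen afterwards so the retained
#' draws come from a fixed kernel). The adapted scale is capped at x10 / /10
#' of the initial scale.
#'
#' @param accepts logical vector of accept/reject outcomes in the window.
#' @param scale current proposal scale multiplier.
#' @param init_scale initial multiplier (anchors the caps).
#' @param target_accept target acceptance rate.
#' @return updated scale multiplier.
#' @export
adapt_proposal <- function(accepts, scale, init_scale = 1, target_accept = 0.3) {
  rate <- mean(accepts)
  min(max(scale * exp(rate - target_accept), init_scale / 10), init_scale * 10)
}

#' Metropolis-Hastings sampling of a patient's conditional distribution
#'
#' Random-walk Metropolis on the log-scale deviations, initialized at the
#' empirical-Bayes mode. The proposal SD per dimension is
#' `scale * 0.5 * prior_sd`, with the common multiplier `scale` adapted
#' toward 30% acceptance during burn-in and frozen afterwards. After burn-in
#' every `thin`-th draw is retained until `n_draws` clones are collected, so
#' the retained draws span `n_draws * thin` iterations.
#'
#' @param target a [conditional_target()].
#' @param n_draws number of clones to retain (default 100).
#' @param burn burn-in iterations.
#' @param thin thinning interval.
#' @param seed RNG seed (same seed + settings => identical clone set).
#' @param adapt_window iterations between adaptation steps during burn-in.
#' @return a `clone_set`: data.frame of complete individual parameter vectors
#'   (one row per clone) with sampler metadata in attributes
#'   (`seed`, `accept_rate`, `burn`, `thin`, `scale`).
#' @export
mh_sample <- function(target, n_draws = 100, burn = 500, thin = 10, seed = 1,
                      adapt_window = 50) {
  stopifnot(inherits(target, "conditional_target"), n_draws >= 1)
  d <- length(target$dims)
  set.seed(seed)
  step0 <- 0.5 * target$prior_sd
  scale <- 1
  cur <- target$eb_mode()
  lp_cur <- target$log_post(cur)
  if (!is.finite(lp_cur)) {
    stop("conditional density not finite at the empirical-Bayes mode for subject ",
         target$patient_id, call. = FALSE)
  }

  total <- burn + thin * n_draws
  draws <- matrix(NA_real_, n_draws, d)
  kept <- 0L
  acc_window <- logical(0)
  acc_post <- 0L
  n_post <- 0L

  for (it in seq_len(total)) {
    prop <- cur + scale * step0 * stats::rnorm(d)
    lp_prop <- target$log_post(prop)
    accept <- is.finite(lp_prop) && log(stats::runif(1)) < (lp_prop - lp_cur)
    if (accept) {
      cur <- prop
      lp_cur <- lp_prop
    }
    if (it <= burn) {
      acc_window <- c(acc_window, accept)
      if (length(acc_window) >= adapt_window) {
        scale <- adapt_proposal(acc_window, scale, init_scale = 1)
        acc_window <- logical(0)
      }
    } else {
      n_post <- n_post + 1L
      acc_post <- acc_post + accept
      if ((it - burn) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- cur
      }
    }
  }

  rate <- acc_post / max(n_post, 1L)
  if (rate < 0.05 || rate > 0.8) {
    warning(sprintf("subject %s: post-burn-in acceptance rate %.2f outside [0.05, 0.8] (scale %.3g)",
                    target$patient_id, rate, scale))
  }
  clones <- do.call(rbind, lapply(seq_len(n_draws),
                                  function(k) target$make_clone(draws[k, ])))
  clones$clone <- seq_len(n_draws)
  eta_extra <- if (d > 2) draws[, 3:d, drop = FALSE] else NULL
  if (!is.null(eta_extra)) {
    colnames(eta_extra) <- target$dims[3:d]
    clones <- cbind(clones, eta_extra)
  }
  structure(clones, class = c("clone_set", "data.frame"),
            seed = seed, accept_rate = rate, burn = burn, thin = thin,
            scale = scale)
}

#' Clone sets for a whole cohort
#'
#' Runs [mh_sample()] per patient with a subject-derived seed and stacks the
#' results.
#'
#' @param cohort a `utk_cohort`.
#' @param model a [pop_model()].
#' @param pk_ind named list of individual PK parameter sets (or
#'   [map_cohort_pk()] output).
#' @param n_draws,burn,thin,sample_pk see [mh_sample()] / [conditional_target()].
#' @param master_seed master seed; per-subject seeds via [derive_seed()].
#' @return data.frame of clones for all patients (class `clone_set`).
#' @export
clone_cohort <- function(cohort, model, pk_ind, n_draws = 100, burn = 500,
                         thin = 10, sample_pk = FALSE, master_seed = 1) {
  sets <- lapply(cohort, function(p) {
    ind <- pk_ind[[as.character(p$id)]]
    if (is.list(ind) && !inherits(ind, "pk_individual")) ind <- ind$ind
    tg <- conditional_target(p, model, ind, sample_pk = sample_pk)
    mh_sample(tg, n_draws = n_draws, burn = burn, thin = thin,
              seed = derive_seed(master_seed, p$id))
  })
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  structure(out, class = c("clone_set", "data.frame"),
            accept_rate = vapply(sets, attr, numeric(1), which = "accept_rate"),
            master_seed = master_seed, burn = burn, thin = thin)
}
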