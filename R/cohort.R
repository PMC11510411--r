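#' Truncated-normal sampler (rejection)
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @return numeric vector inside `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop("infeasible truncation bounds", call. = FALSE)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Current-treatment regimen frequencies observed in the 23-patient cohort
# (dose mg, interval weeks, count).
default_regimen_table <- function() {
  data.frame(
    dose = c(45, 90, 45, 45, 45, 90, 90, 90, 90, 90),
    interval = c(12, 12, 14, 16, 18, 14, 15, 16, 10, 8),
    n = c(1, 8, 1, 3, 1, 1, 2, 3, 1, 2)
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' Encodes the statistical structure of the observed cohort: truncated-normal
#' body weight 92 +/- 18.4 kg on \[70, 135\], truncated-normal observed
#' baseline PASI 14.4 +/- 6.23 on \[5, 31.9\], the empirical current-regimen
#' frequency table, sparse therapeutic-drug-monitoring PK sampling (pre-dose
#' trough plus scheduled weeks 2, 6, 10, 12, 14, 16, 18 after an anchor dose,
#' thinned to 2–5 samples per patient, mean ~3.3), PASI visits every 3 months
#' in year one then every 6 months, and the assay quantification range
#' 0.63–20 mg/L. `pd_times` may be overridden (e.g. biweekly) for
#' rich-sampling simulation studies.
#'
#' @param n number of patients.
#' @param model true population PK/PD model ([pop_model()]).
#' @param weight_mean,weight_sd,weight_range body-weight distribution (kg).
#' @param pasi0_mean,pasi0_sd,pasi0_range observed-baseline-PASI distribution.
#' @param regimen_table data.frame (dose, interval, n) of current regimens.
#' @param followup_days follow-up horizon (days).
#' @param pk_template_weeks PK sampling template, weeks relative to the anchor
#'   dose (0 = pre-dose trough).
#' @param pk_n_range inclusive range of PK samples per patient.
#' @param pk_n_mean target mean PK samples per patient.
#' @param pd_times PASI observation times (days, > 0).
#' @param loq,uloq lower/upper assay quantification limits (mg/L).
#' @param pk_iiv_dims names of PK parameters given simulated IIV.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 23,
                          model = pop_model(),
                          weight_mean = 92, weight_sd = 18.4,
                          weight_range = c(70, 135),
                          pasi0_mean = 14.4, pasi0_sd = 6.23,
                          pasi0_range = c(5, 31.9),
                          regimen_table = default_regimen_table(),
                          followup_days = 546,
                          pk_template_weeks = c(0, 2, 6, 10, 12, 14, 16, 18),
                          pk_n_range = c(2L, 5L),
                          pk_n_mean = 75 / 23,
                          pd_times = c(91, 182, 273, 364, 546),
                          loq = 0.63, uloq = 20,
                          pk_iiv_dims = c("CL", "V2")) {
  stopifnot(n >= 1, inherits(model, "pop_model"))
  if (weight_range[1] >= weight_range[2] || pasi0_range[1] >= pasi0_range[2]) {
    stop("infeasible truncation bounds", call. = FALSE)
  }
  if (any(regimen_table$n <= 0) || sum(regimen_table$n) <= 0) {
    stop("regimen frequencies must be positive", call. = FALSE)
  }
  structure(list(
    n = as.integer(n), model = model,
    weight_mean = weight_mean, weight_sd = weight_sd, weight_range = weight_range,
    pasi0_mean = pasi0_mean, pasi0_sd = pasi0_sd, pasi0_range = pasi0_range,
    regimen_table = regimen_table, followup_days = followup_days,
    pk_template_weeks = pk_template_weeks, pk_n_range = as.integer(pk_n_range),
    pk_n_mean = pk_n_mean, pd_times = pd_times, loq = loq, uloq = uloq,
    pk_iiv_dims = pk_iiv_dims
  ), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws covariates, individual random effects and a current regimen per
#' patient, simulates the latent PK/PD trajectories under that regimen, adds
#' proportional PK noise and multiplicative log-normal PASI noise, and flags
#' assay censoring. Fully reproducible from `seed`. Hidden truths (true
#' parameters and latent values) are recorded on each patient and summarised
#' by [truth_report()].
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return object of class `utk_cohort`: a list of patients, each a list with
#'   `id`, `weight`, `pasi0` (observed baseline), `regimen`, `doses`,
#'   `pk_obs` (`time`, `dv`, `cens`, `latent`), `pd_obs` (`time`, `dv`,
#'   `latent`) and a `truth` record.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  model <- config$model
  pk <- model$pk

  rt <- config$regimen_table
  reg_idx <- sample.int(nrow(rt), config$n, replace = TRUE, prob = rt$n / sum(rt$n))

  patients <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    weight <- rtruncnorm(1, config$weight_mean, config$weight_sd,
                         config$weight_range[1], config$weight_range[2])
    pasi0_obs <- rtruncnorm(1, config$pasi0_mean, config$pasi0_sd,
                            config$pasi0_range[1], config$pasi0_range[2])
    eta_rv <- stats::rnorm(1, 0, model$sigma_pd)
    pasi0_true <- pasi0_obs * exp(eta_rv)
    eta_kout <- stats::rnorm(1, 0, model$omega_kout)
    kout_i <- model$kout_pop * exp(eta_kout)

    eta_pk <- stats::setNames(numeric(length(config$pk_iiv_dims)), config$pk_iiv_dims)
    for (d in config$pk_iiv_dims) eta_pk[[d]] <- stats::rnorm(1, 0, pk$omega[[d]])
    ind <- apply_covariates(pk, weight, eta_pk)

    cur <- regimen(rt$dose[reg_idx[i]], rt$interval[reg_idx[i]],
                   n_cycles = ceiling(config$followup_days /
                                        weeks_to_days(rt$interval[reg_idx[i]])) + 1L)
    doses <- regimen_doses(cur)
    doses <- doses[doses$time <= config$followup_days, , drop = FALSE]

    # PK sampling: template anchored at the maintenance dose nearest mid follow-up
    anchor <- doses$time[which.min(abs(doses$time - config$followup_days / 3))]
    tpl <- anchor + weeks_to_days(config$pk_template_weeks)
    tpl <- unique(pmin(tpl, config$followup_days))
    lo <- config$pk_n_range[1]; hi <- config$pk_n_range[2]
    n_pk <- lo + stats::rbinom(1, hi - lo, (config$pk_n_mean - lo) / (hi - lo))
    n_pk <- min(n_pk, length(tpl))
    t_pk <- sort(sample(tpl, n_pk))

    c_lat <- pk_concentration(ind, doses, t_pk)
    c_obs <- c_lat * exp(stats::rnorm(n_pk, 0, pk$sigma_prop))
    cens <- ifelse(c_obs < config$loq, 1L, ifelse(c_obs > config$uloq, 2L, 0L))

    t_pd <- config$pd_times[config$pd_times <= config$followup_days]
    pdp <- pd_params(kout_i, model$Imax_pop, model$IC50, pasi0_true)
    p_lat <- pd_trajectory(pdp, function(tt) pk_concentration(ind, doses, tt),
                           t_pd, h = 0.25)
    p_obs <- p_lat * exp(stats::rnorm(length(t_pd), 0, model$sigma_pd))

    patients[[i]] <- list(
      id = i, weight = weight, pasi0 = pasi0_obs, regimen = cur, doses = doses,
      pk_obs = data.frame(time = t_pk, dv = c_obs, cens = cens, latent = c_lat),
      pd_obs = data.frame(time = t_pd, dv = p_obs, latent = p_lat),
      truth = list(pasi0_true = pasi0_true, eta_rv = eta_rv,
                   eta_kout = eta_kout, kout = kout_i,
                   eta_pk = as.list(eta_pk), pk = ind)
    )
  }
  structure(patients, class = "utk_cohort",
            seed = seed, config = config)
}

#' Table of hidden truths for a generated cohort
#'
#' @param cohort a cohort from [generate_cohort()].
#' @return data.frame, one row per patient, with true individual parameters
#'   and the latent PASI at the last observation time.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "utk_cohort"))
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(
      id = p$id, weight = p$weight, pasi0_obs = p$pasi0,
      pasi0_true = p$truth$pasi0_true, eta_rv = p$truth$eta_rv,
      eta_kout = p$truth$eta_kout, kout = p$truth$kout,
      CL = p$truth$pk$CL, V2 = p$truth$pk$V2,
      regimen = format(p$regimen),
      n_pk = nrow(p$pk_obs), n_blq = sum(p$pk_obs$cens == 1L),
      n_pd = nrow(p$pd_obs),
      pasi_end_latent = utils::tail(p$pd_obs$latent, 1)
    )
  }))
}
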