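# Shared fixtures and independent numerical oracles used across tests.

typical_pk <- function() pk_individual(ka = 0.35, CL = 0.465, Q = 0.4,
                                       V2 = 4.6, V3 = 2.8)

typical_pd <- function(PASI0 = 14.4) pd_params(kout = 0.016, Imax = 0.97,
                                               IC50 = 0.07, PASI0 = PASI0)

# Numeric ODE oracle for the full dosing system: depot, central, peripheral
# amounts plus a cumulative eliminated amount (mass-balance bookkeeping).
# Doses are injected into the depot via events. Returns a function of time for
# the central concentration plus the raw deSolve matrix.
pk_ode_oracle <- function(ind, doses, t_out, rtol = 1e-10, atol = 1e-12) {
  k10 <- ind$CL / ind$V2
  k12 <- ind$Q / ind$V2
  k21 <- ind$Q / ind$V3
  deriv <- function(t, y, p) {
    list(c(-ind$ka * y[1],
           ind$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3],
           k10 * y[2]))
  }
  a1_0 <- ind$F * sum(doses$amt[doses$time == 0])
  later <- doses[doses$time > 0, , drop = FALSE]
  ev <- if (nrow(later)) {
    list(data = data.frame(var = "A1", time = later$time,
                           value = ind$F * later$amt, method = "add"))
  } else NULL
  times <- sort(unique(c(0, doses$time, t_out)))
  sol <- deSolve::lsoda(c(A1 = a1_0, A2 = 0, A3 = 0, Ael = 0), times, deriv,
                        parms = NULL, events = ev, rtol = rtol, atol = atol)
  list(conc = sol[match(t_out, sol[, "time"]), "A2"] / ind$V2, sol = sol)
}

# Tiny patient constructor for estimation / sampler tests.
make_patient <- function(id, weight, pasi0, doses, pk_obs = NULL, pd_obs = NULL,
                         reg = regimen(90, 12, n_cycles = max(1L, nrow(doses)))) {
  list(id = id, weight = weight, pasi0 = pasi0, regimen = reg, doses = doses,
       pk_obs = pk_obs %||% data.frame(time = numeric(0), dv = numeric(0),
                                       cens = integer(0)),
       pd_obs = pd_obs %||% data.frame(time = numeric(0), dv = numeric(0)),
       truth = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_cohort <- function(patients) structure(patients, class = "utk_cohort")

# Conjugate normal-normal target with a closed-form posterior, shaped like a
# conditional_target so it can drive mh_sample() directly.
toy_target <- function(y, prior_sd = 1, lik_sd = 0.5) {
  prec <- 1 / prior_sd^2 + length(y) / lik_sd^2
  post_mean <- (sum(y) / lik_sd^2) / prec
  structure(list(
    dims = "eta", prior_sd = prior_sd, patient_id = 0,
    post_mean = post_mean, post_sd = sqrt(1 / prec),
    log_post = function(e) sum(dnorm(y, e, lik_sd, log = TRUE)) +
      dnorm(e, 0, prior_sd, log = TRUE),
    eb_mode = function() post_mean,
    make_clone = function(e) data.frame(id = 0, ka = 1, F = 1, CL = 1, Q = 1,
                                        V2 = 1, V3 = 1, kout = 1, Imax = 1,
                                        IC50 = 1, PASI0 = 1,
                                        eta_kout = e[1], eta_rv = 0)
  ), class = "conditional_target")
}
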