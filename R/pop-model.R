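#' Population PK/PD model
#'
#' Bundles the PK population layer with the PD fixed effects, the single PD
#' random effect (log-normal IIV on `kout`), and the residual-error models.
#' The PD residual is multiplicative log-normal: observed PASI
#' `y = PASI(t) * exp(sigma_pd * eps)`. The individual baseline enters via the
#' B2 method, `PASI_i = PASI_i0 * exp(eta_RV)` with `eta_RV` constrained to
#' the residual variance `sigma_pd^2`. `IC50` is a fixed constant, excluded
#' from estimation.
#'
#' Defaults are the final population estimates for ustekinumab in plaque
#' psoriasis: `kout = 0.016`/day, `Imax = 0.97`, `IC50 = 0.07` mg/L (fixed),
#' `omega_kout = 0.5587` (log-SD), PD residual log-SD `0.86`.
#'
#' @param pk a [pk_population()].
#' @param kout_pop population remission rate (1/day).
#' @param Imax_pop population maximum inhibition, in (0, 1].
#' @param IC50 fixed half-maximal concentration (mg/L).
#' @param omega_kout log-scale IIV SD of `kout` (>= 0).
#' @param sigma_pd log-scale SD of the multiplicative PD residual (> 0).
#' @return object of class `pop_model`.
#' @export
pop_model <- function(pk = pk_population(), kout_pop = 0.016, Imax_pop = 0.97,
                      IC50 = 0.07, omega_kout = 0.5587, sigma_pd = 0.86) {
  stopifnot(inherits(pk, "pk_population"))
  assert_positive(c(kout_pop, IC50), "kout_pop/IC50")
  # sigma_pd = 0 is admitted only to simulate noise-free cohorts; estimation
  # keeps sigma_pd strictly positive through its bounds
  assert_nonneg(c(omega_kout, sigma_pd), "omega_kout/sigma_pd")
  if (Imax_pop <= 0 || Imax_pop > 1) stop("`Imax_pop` must lie in (0, 1]", call. = FALSE)
  structure(
    list(pk = pk, kout_pop = kout_pop, Imax_pop = Imax_pop, IC50 = IC50,
         omega_kout = omega_kout, sigma_pd = sigma_pd, IC50_fixed = TRUE),
    class = "pop_model"
  )
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK/PD model (PASI turnover with Imax inhibition)\n")
  cat(sprintf("  kout = %g /day, Imax = %g, IC50 = %g mg/L (fixed)\n",
              x$kout_pop, x$Imax_pop, x$IC50))
  cat(sprintf("  IIV: omega(kout) = %g (log-SD); PD residual log-SD = %g\n",
              x$omega_kout, x$sigma_pd))
  invisible(x)
}
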