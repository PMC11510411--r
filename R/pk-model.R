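#' Population PK parameter set for subcutaneous ustekinumab
#'
#' Typical values, allometric body-weight exponents, inter-individual
#' variability (IIV, log-scale SDs) and the proportional residual-error SD of
#' a two-compartment model with first-order subcutaneous absorption.
#'
#' Under subcutaneous-only dosing the bioavailability `F` is not separately
#' identifiable, so the default parameterization is apparent (`CL/F`, `Q/F`,
#' `V2/F`, `V3/F`) with `F = 1`; set `F < 1` explicitly to work on the
#' absolute scale.
#'
#' The shipped typical values are illustrative defaults for testing and
#' simulation; for real use supply the literature values of the integrated
#' ustekinumab population model you rely on. The default IIV (log-SD 0.3 on
#' CL and V2) is likewise illustrative.
#'
#' @param ka first-order absorption rate constant (1/day).
#' @param CL apparent clearance (L/day).
#' @param Q apparent intercompartmental clearance (L/day).
#' @param V2 apparent central volume (L).
#' @param V3 apparent peripheral volume (L).
#' @param F bioavailability fraction in (0, 1].
#' @param allometric named vector of body-weight power exponents.
#' @param ref_weight reference body weight (kg).
#' @param omega named vector of log-scale IIV SDs (>= 0).
#' @param sigma_prop residual-error SD for PK observations: log-normal
#'   (exponential-proportional) error, approximately the proportional CV for
#'   small values.
#' @return an object of class `pk_population`.
#' @export
pk_population <- function(ka = 0.35, CL = 0.465, Q = 0.4, V2 = 4.6, V3 = 2.8,
                          F = 1,
                          allometric = c(CL = 0.75, Q = 0.75, V2 = 1, V3 = 1),
                          ref_weight = 70,
                          omega = c(ka = 0, CL = 0.3, Q = 0, V2 = 0.3, V3 = 0),
                          sigma_prop = 0.2) {
  assert_positive(c(ka, CL, Q, V2, V3), "typical values")
  assert_positive(ref_weight, "ref_weight")
  assert_nonneg(sigma_prop, "sigma_prop") # 0 only for degenerate simulation
  if (F <= 0 || F > 1) stop("`F` must lie in (0, 1]", call. = FALSE)
  assert_nonneg(omega, "omega")
  structure(
    list(ka = ka, CL = CL, Q = Q, V2 = V2, V3 = V3, F = F,
         allometric = allometric, ref_weight = ref_weight,
         omega = omega, sigma_prop = sigma_prop),
    class = "pk_population"
  )
}

#' Individual PK parameter set
#'
#' @param ka absorption rate constant (1/day).
#' @param CL clearance (L/day).
#' @param Q intercompartmental clearance (L/day).
#' @param V2 central volume (L).
#' @param V3 peripheral volume (L).
#' @param F bioavailability in (0, 1].
#' @return an object of class `pk_individual`.
#' @export
pk_individual <- function(ka, CL, Q, V2, V3, F = 1) {
  assert_positive(c(ka, CL, Q, V2, V3), "PK parameters")
  if (F <= 0 || F > 1) stop("`F` must lie in (0, 1]", call. = FALSE)
  structure(list(ka = ka, CL = CL, Q = Q, V2 = V2, V3 = V3, F = F),
            class = "pk_individual")
}

#' Apply body-weight covariate and random effects to the typical individual
#'
#' Each disposition parameter scales allometrically,
#' `P_i = P_typ * (WT / WT_ref)^exponent * exp(eta_P)`; parameters without an
#' entry in `allometric` (notably `ka`) carry exponent 0.
#'
#' @param pop a [pk_population()].
#' @param weight_kg body weight (kg), strictly positive.
#' @param eta optional named vector of log-scale deviations
#'   (names among `ka`, `CL`, `Q`, `V2`, `V3`); missing entries are 0.
#' @return a [pk_individual()].
#' @export
apply_covariates <- function(pop, weight_kg, eta = NULL) {
  stopifnot(inherits(pop, "pk_population"))
  if (!is.numeric(weight_kg) || length(weight_kg) != 1 ||
      !is.finite(weight_kg) || weight_kg <= 0) {
    stop("`weight_kg` must be a single positive number", call. = FALSE)
  }
  full_eta <- c(ka = 0, CL = 0, Q = 0, V2 = 0, V3 = 0)
  if (!is.null(eta)) {
    if (any(!is.finite(eta))) stop("`eta` must be finite", call. = FALSE)
    bad <- setdiff(names(eta), names(full_eta))
    if (length(bad)) stop("unknown eta dimension(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    full_eta[names(eta)] <- eta
  }
  wr <- weight_kg / pop$ref_weight
  scaled <- vapply(names(full_eta), function(p) {
    expo <- if (p %in% names(pop$allometric)) pop$allometric[[p]] else 0
    pop[[p]] * wr^expo * exp(full_eta[[p]])
  }, numeric(1))
  pk_individual(ka = scaled[["ka"]], CL = scaled[["CL"]], Q = scaled[["Q"]],
                V2 = scaled[["V2"]], V3 = scaled[["V3"]], F = pop$F)
}

# Disposition eigenvalues (macro rate constants) of the linear two-compartment
# system. lambda1 > lambda2 > 0.
disposition_eigen <- function(ind) {
  k10 <- ind$CL / ind$V2
  k12 <- ind$Q / ind$V2
  k21 <- ind$Q / ind$V3
  s <- k10 + k12 + k21
  disc <- sqrt(s * s - 4 * k10 * k21)
  list(l1 = (s + disc) / 2, l2 = (s - disc) / 2, k21 = k21)
}

#' Central concentration under multiple subcutaneous doses
#'
#' Closed-form tri-exponential solution of the linear two-compartment model
#' with first-order absorption, superposed over all doses administered at or
#' before each evaluation time. A dose given exactly at `t` contributes 0 at
#' `t` (the returned value is the trough with respect to that dose).
#'
#' When the absorption rate constant collides with a disposition eigenvalue
#' the coefficients are degenerate; `ka` is then nudged by a machine-safe
#' relative epsilon instead of dividing by zero.
#'
#' @param ind a [pk_individual()].
#' @param doses data.frame with columns `time` (days, sorted) and `amt` (mg).
#' @param t numeric vector of evaluation times (days, >= 0).
#' @return numeric vector of concentrations (mg/L), same length as `t`.
#' @export
pk_concentration <- function(ind, doses, t) {
  stopifnot(inherits(ind, "pk_individual"))
  if (!all(is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0", call. = FALSE)
  if (nrow(doses) == 0) return(numeric(length(t)))
  if (is.unsorted(doses$time)) stop("dose events must be sorted by time", call. = FALSE)
  if (any(doses$amt < 0)) stop("dose amounts must be >= 0", call. = FALSE)

  eig <- disposition_eigen(ind)
  ka <- ind$ka
  # guard against eigenvalue collision
  tol <- 1e-8 * max(ka, eig$l1)
  if (min(abs(ka - eig$l1), abs(ka - eig$l2)) < tol) ka <- ka * (1 + 1e-7)
  l1 <- eig$l1; l2 <- eig$l2; k21 <- eig$k21
  A <- (k21 - l1) / ((ka - l1) * (l2 - l1))
  B <- (k21 - l2) / ((ka - l2) * (l1 - l2))
  C3 <- (k21 - ka) / ((l1 - ka) * (l2 - ka))
  scale <- ind$F * ka / ind$V2

  dt <- outer(t, doses$time, "-")
  pos <- dt > 0
  dtp <- ifelse(pos, dt, 0)
  prof <- A * exp(-l1 * dtp) + B * exp(-l2 * dtp) + C3 * exp(-ka * dtp)
  prof[!pos] <- 0
  conc <- as.vector(prof %*% doses$amt) * scale
  pmax(conc, 0) # clip tiny negative round-off
}
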