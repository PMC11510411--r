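# ---- clone-based MIPD engine ----

#' Simulate current-then-candidate dosing cycles for a clone set
#'
#' Each clone (a complete individual parameter vector) is simulated
#' deterministically — no residual noise on the latent PASI — through
#' `n_current` cycles of the current regimen followed by `n_candidate` cycles
#' of the candidate; cycle length equals the interval of the regimen being
#' administered, and the PD state is continuous across the switch. Evaluation
#' is at the trough instant at the end of the 5th and 10th cycle (the moment
#' before the next scheduled dose).
#'
#' @param clones a `clone_set` for one patient.
#' @param current the patient's current [regimen()].
#' @param candidate the candidate [regimen()] (dose 0 encodes washout).
#' @param n_current,n_candidate cycles of each regimen.
#' @param h PD solver grid step (days).
#' @return data.frame, one row per clone: `id`, `clone`, `pasi_c5`,
#'   `ctrough_c5`, `pasi_c10`, `ctrough_c10`.
#' @export
simulate_cycles <- function(clones, current, candidate,
                            n_current = 5L, n_candidate = 5L, h = 0.5) {
  stopifnot(inherits(current, "regimen"), inherits(candidate, "regimen"))
  if (nrow(clones) == 0) stop("empty clone set", call. = FALSE)
  tau1 <- weeks_to_days(current$interval_weeks)
  tau2 <- weeks_to_days(candidate$interval_weeks)
  t_switch <- n_current * tau1
  t_end <- t_switch + n_candidate * tau2
  doses <- data.frame(
    time = c((seq_len(n_current) - 1L) * tau1,
             t_switch + (seq_len(n_candidate) - 1L) * tau2),
    amt = c(rep(current$dose_mg, n_current), rep(candidate$dose_mg, n_candidate))
  )
  grid <- uniform_grid(t_end, h)
  hg <- grid[2] - grid[1]
  t_eval <- c(t_switch, t_end)
  interp <- grid_interp_setup(grid, t_eval)

  pk_key <- paste(clones$ka, clones$CL, clones$Q, clones$V2, clones$V3, clones$F)
  uniq <- !duplicated(pk_key)
  conc_grid <- list()
  conc_eval <- list()
  for (i in which(uniq)) {
    ind <- pk_individual(clones$ka[i], clones$CL[i], clones$Q[i],
                         clones$V2[i], clones$V3[i], clones$F[i])
    conc_grid[[pk_key[i]]] <- pk_concentration(ind, doses, grid)
    conc_eval[[pk_key[i]]] <- pk_concentration(ind, doses, t_eval)
  }

  out <- data.frame(id = clones$id, clone = clones$clone,
                    pasi_c5 = NA_real_, ctrough_c5 = NA_real_,
                    pasi_c10 = NA_real_, ctrough_c10 = NA_real_)
  for (i in seq_len(nrow(clones))) {
    Cg <- conc_grid[[pk_key[i]]]
    Ig <- clones$Imax[i] * Cg / (clones$IC50[i] + Cg)
    pasi <- pasi_on_grid(clones$kout[i], clones$PASI0[i], Ig, hg)
    if (any(!is.finite(pasi))) {
      stop("PD solution failed for clone ", clones$clone[i], call. = FALSE)
    }
    pv <- grid_interp(pasi, interp)
    ce <- conc_eval[[pk_key[i]]]
    out$pasi_c5[i] <- pv[1]; out$ctrough_c5[i] <- ce[1]
    out$pasi_c10[i] <- pv[2]; out$ctrough_c10[i] <- ce[2]
  }
  out
}

#' Probability of target attainment across clones
#'
#' Exact counting: `probability = 100 * nPASI / TPASI`, where `nPASI` is the
#' number of simulated PASI values at or below the target (the boundary is
#' inclusive) and `TPASI` the total number of clones.
#'
#' @param pasi_values per-clone PASI values (non-empty).
#' @param target response target (default absolute PASI <= 1).
#' @return list with `npasi`, `tpasi`, `probability` (percent).
#' @export
probability_target <- function(pasi_values, target = 1.0) {
  if (length(pasi_values) == 0) stop("no PASI values supplied", call. = FALSE)
  if (any(!is.finite(pasi_values))) stop("non-finite PASI values", call. = FALSE)
  n <- sum(pasi_values <= target)
  list(npasi = n, tpasi = length(pasi_values),
       probability = 100 * n / length(pasi_values))
}

#' Select a dosing regimen under the probability threshold rule
#'
#' Candidates reaching `probability >= threshold` qualify; if none qualifies
#' the patient is classified as a therapeutic `failure`. Among qualifiers the
#' regimen with minimal dose intensity (mg/week) is selected — the
#' "optimized" preference — with ties broken toward the longer interval
#' (fewer injections). The selection is classified against the current
#' regimen: same regimen `maintain`, lower intensity `optimize`, higher
#' intensity `intensify`; at equal intensity but a different regimen, a
#' longer interval counts as `optimize`, otherwise `intensify`.
#'
#' @param probs data.frame with columns `dose`, `interval` (weeks) and
#'   `probability` (percent), covering the full candidate grid.
#' @param current the current [regimen()].
#' @param threshold qualification threshold in percent (default 90).
#' @return list (class `mipd_decision`): `selected` ([regimen()] or `NULL`),
#'   `classification`, `probabilities`.
#' @export
select_regimen <- function(probs, current, threshold = 90) {
  stopifnot(all(c("dose", "interval", "probability") %in% names(probs)),
            inherits(current, "regimen"))
  probs$intensity <- probs$dose / probs$interval
  qual <- probs[probs$probability >= threshold, , drop = FALSE]
  if (nrow(qual) == 0) {
    return(structure(list(selected = NULL, classification = "failure",
                          probabilities = probs), class = "mipd_decision"))
  }
  qual <- qual[order(qual$intensity, -qual$interval), , drop = FALSE]
  sel <- regimen(qual$dose[1], qual$interval[1])
  cur_int <- dose_intensity(current)
  sel_int <- dose_intensity(sel)
  classification <-
    if (sel$dose_mg == current$dose_mg &&
        sel$interval_weeks == current$interval_weeks) "maintain"
    else if (sel_int < cur_int) "optimize"
    else if (sel_int > cur_int) "intensify"
    else if (sel$interval_weeks > current$interval_weeks) "optimize"
    else "intensify"
  structure(list(selected = sel, classification = classification,
                 probabilities = probs), class = "mipd_decision")
}

#' MIPD decisions for a cohort of clone sets
#'
#' For every patient, simulates 5 cycles of the current regimen followed by 5
#' cycles of each candidate in the grid, computes the cycle-10
#' probability of absolute PASI <= `target` across clones (and the cycle-5
#' probability under the current regimen), and applies the >= `threshold`
#' selection rule.
#'
#' @param cohort a `utk_cohort` (supplies the current regimens).
#' @param clones stacked `clone_set` from [clone_cohort()].
#' @param grid candidate list from [regimen_grid()].
#' @param target PASI response target.
#' @param threshold selection threshold (percent).
#' @param h PD solver grid step (days).
#' @return list: `decisions` (one row per patient), `probabilities` (long,
#'   patient x candidate), `records` (per-clone exposure/response at cycle
#'   10, input to [exposure_response_table()]).
#' @export
mipd_decide <- function(cohort, clones, grid = regimen_grid(), target = 1.0,
                        threshold = 90, h = 0.5) {
  if (length(grid) == 0) stop("empty candidate grid", call. = FALSE)
  dec_rows <- list(); prob_rows <- list(); rec_rows <- list()
  for (p in cohort) {
    cl <- clones[clones$id == p$id, , drop = FALSE]
    if (nrow(cl) == 0) stop("no clones for subject ", p$id, call. = FALSE)
    probs <- data.frame(dose = numeric(0), interval = numeric(0),
                        probability = numeric(0))
    prob5 <- NA_real_
    sel_trough <- list()
    for (cand in grid) {
      sim <- simulate_cycles(cl, p$regimen, cand, h = h)
      pr <- probability_target(sim$pasi_c10, target)
      lbl <- format(cand)
      probs <- rbind(probs, data.frame(dose = cand$dose_mg,
                                       interval = cand$interval_weeks,
                                       probability = pr$probability))
      if (is.na(prob5)) {
        prob5 <- probability_target(sim$pasi_c5, target)$probability
      }
      sel_trough[[lbl]] <- stats::median(sim$ctrough_c10)
      rec_rows[[length(rec_rows) + 1L]] <-
        data.frame(id = p$id, regimen = lbl, dose = cand$dose_mg,
                   interval = cand$interval_weeks, clone = sim$clone,
                   ctrough = sim$ctrough_c10, pasi = sim$pasi_c10)
    }
    d <- select_regimen(probs, p$regimen, threshold)
    sel_lbl <- if (is.null(d$selected)) NA_character_ else format(d$selected)
    dec_rows[[length(dec_rows) + 1L]] <- data.frame(
      id = p$id, current = format(p$regimen), selected = sel_lbl,
      classification = d$classification, prob5_current = prob5,
      best_prob10 = max(probs$probability),
      ctrough_ss = if (is.na(sel_lbl)) NA_real_ else sel_trough[[sel_lbl]]
    )
    probs$id <- p$id
    prob_rows[[length(prob_rows) + 1L]] <- probs
  }
  list(decisions = do.call(rbind, dec_rows),
       probabilities = do.call(rbind, prob_rows),
       records = do.call(rbind, rec_rows))
}

#' Exposure-response table across regimens
#'
#' Pairs each clone's steady-state trough concentration with its absolute
#' PASI at cycle 10, for every patient and candidate regimen, together with
#' per-regimen summaries (median trough, fraction of clones at target).
#'
#' @param records the `records` element of [mipd_decide()].
#' @param target PASI target for the summary fraction.
#' @return list: `records` (as given), `summary` (one row per regimen, sorted
#'   by dose intensity).
#' @export
exposure_response_table <- function(records, target = 1.0) {
  stopifnot(all(c("regimen", "ctrough", "pasi") %in% names(records)))
  spl <- split(records, records$regimen)
  summary <- do.call(rbind, lapply(spl, function(d) {
    data.frame(regimen = d$regimen[1], dose = d$dose[1], interval = d$interval[1],
               intensity = d$dose[1] / d$interval[1],
               median_ctrough = stats::median(d$ctrough),
               frac_at_target = mean(d$pasi <= target))
  }))
  summary <- summary[order(summary$intensity, -summary$interval), ]
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' Regimen-flow table (current to selected)
#'
#' Counts of patients per (current regimen, selected regimen) pair, ready for
#' a Sankey-style flow display; failures appear under selected = "none".
#'
#' @param decisions the `decisions` element of [mipd_decide()].
#' @return data.frame with `current`, `selected`, `n`.
#' @export
flow_table <- function(decisions) {
  sel <- ifelse(is.na(decisions$selected), "none", decisions$selected)
  out <- as.data.frame(table(current = decisions$current, selected = sel),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  out[out$n > 0, ]
}

#' Annual dose count and drug cost of a regimen
#'
#' First treatment year: induction doses at weeks 0 and 4, then maintenance
#' spacing, counting doses in weeks `[0, 52)`. Maintenance year:
#' `floor(52 / interval)` doses. Cost is count times the per-dose price
#' (EUR 2915.4 for the 45 mg pre-filled syringe).
#'
#' @param reg a [regimen()].
#' @param price price per dose (EUR).
#' @param year `"first"` or `"maintenance"`.
#' @return list with `n_doses` and `cost` (EUR).
#' @export
annual_cost <- function(reg, price = 2915.4, year = c("first", "maintenance")) {
  stopifnot(inherits(reg, "regimen"))
  assert_positive(price, "price")
  year <- match.arg(year)
  tau <- reg$interval_weeks
  n <- if (year == "first") {
    w <- c(0, 4)
    nxt <- 4 + tau
    while (nxt < 52) {
      w <- c(w, nxt)
      nxt <- nxt + tau
    }
    length(w)
  } else {
    floor(52 / tau)
  }
  list(n_doses = as.integer(n), cost = n * price)
}

#' Percent saving when switching regimens
#'
#' `100 * (1 - doses(to) / doses(from))` over the chosen year type; by
#' construction scale-invariant in the per-dose price.
#'
#' @param from,to [regimen()] objects.
#' @param year `"first"` or `"maintenance"`.
#' @return percent saving (negative if `to` costs more).
#' @export
cost_saving <- function(from, to, year = "maintenance") {
  100 * (1 - annual_cost(to, year = year)$n_doses /
           annual_cost(from, year = year)$n_doses)
}
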