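#' Prediction-corrected visual predictive check (PASI)
#'
#' Simulation-based diagnostic of the population PD model. Every observed and
#' simulated PASI value is rescaled by `median(PRED in its time bin) / PRED`,
#' where `PRED` is the population prediction (random effects at zero) for
#' that record; observed 5th/50th/95th percentiles per bin are then compared
#' with confidence bands of the same percentiles across `n_sim` simulated
#' replicates of the original design.
#'
#' @param model a [pop_model()].
#' @param cohort a `utk_cohort`.
#' @param pk_ind named list of individual PK parameter sets.
#' @param n_sim number of simulated replicates (>= 100).
#' @param bins either an integer number of quantile time bins or a numeric
#'   vector of bin breaks (days). Empty bins are merged with their left
#'   neighbour (with a message).
#' @param seed RNG seed (fixed seed gives identical output tables).
#' @param ci level of the simulated percentile bands.
#' @param h PD solver grid step (days).
#' @return object of class `pcvpc`: a plot-ready data.frame `table` with one
#'   row per (bin, percentile): observed value, simulated band lo/hi.
#' @export
pcvpc <- function(model, cohort, pk_ind, n_sim = 200, bins = 4, seed = 1,
                  ci = 0.9, h = 0.5) {
  stopifnot(inherits(model, "pop_model"))
  if (n_sim < 100) stop("`n_sim` must be >= 100", call. = FALSE)

  subs <- pd_fit_data(cohort, pk_ind, h = h, pasi_floor = 1e-6)
  # population predictions (eta = 0) per record
  pred <- list(); tim <- list()
  for (s in subs) {
    Ig <- model$Imax_pop * s$Cgrid / (model$IC50 + s$Cgrid)
    pasi <- pasi_on_grid(model$kout_pop, s$pasi0, Ig, s$hg)
    pred[[length(pred) + 1L]] <- stats::approx(s$grid, pasi, s$tobs, rule = 2)$y
    tim[[length(tim) + 1L]] <- s$tobs
  }
  PRED <- unlist(pred)
  tobs <- unlist(tim)
  yobs <- unlist(lapply(subs, `[[`, "y"))

  # time bins
  if (length(bins) == 1) {
    br <- unique(stats::quantile(tobs, probs = seq(0, 1, length.out = bins + 1)))
  } else {
    br <- sort(unique(bins))
  }
  bin <- findInterval(tobs, br, rightmost.closed = TRUE, all.inside = TRUE)
  # merge empty bins leftward
  counts <- tabulate(bin, nbins = length(br) - 1)
  if (any(counts == 0)) {
    message("pcvpc: merging ", sum(counts == 0), " empty bin(s) with neighbours")
    keep <- which(counts > 0)
    bin <- vapply(bin, function(b) which.min(abs(keep - b)), integer(1))
    bin <- keep[bin]
    bin <- match(bin, keep)
    counts <- counts[keep]
  }
  nb <- max(bin)
  med_pred <- vapply(seq_len(nb), function(b) stats::median(PRED[bin == b]),
                     numeric(1))
  pc_obs <- yobs * med_pred[bin] / PRED

  qs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(seq_len(nb), function(b)
    stats::quantile(pc_obs[bin == b], qs, names = FALSE), numeric(3)))

  set.seed(seed)
  sim_pct <- array(NA_real_, c(n_sim, nb, 3))
  for (r in seq_len(n_sim)) {
    ysim <- unlist(lapply(subs, function(s) {
      eta_k <- stats::rnorm(1, 0, model$omega_kout)
      eta_rv <- stats::rnorm(1, 0, model$sigma_pd)
      Ig <- model$Imax_pop * s$Cgrid / (model$IC50 + s$Cgrid)
      pasi <- pasi_on_grid(model$kout_pop * exp(eta_k),
                           s$pasi0 * exp(eta_rv), Ig, s$hg)
      lat <- stats::approx(s$grid, pasi, s$tobs, rule = 2)$y
      lat * exp(stats::rnorm(length(lat), 0, model$sigma_pd))
    }))
    pc_sim <- ysim * med_pred[bin] / PRED
    for (b in seq_len(nb)) {
      sim_pct[r, b, ] <- stats::quantile(pc_sim[bin == b], qs, names = FALSE)
    }
  }
  alpha <- (1 - ci) / 2
  tab <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(
      bin = b, t_median = stats::median(tobs[bin == b]), n = sum(bin == b),
      percentile = 100 * qs, observed = obs_pct[b, ],
      sim_lo = apply(sim_pct[, b, , drop = FALSE], 3, stats::quantile,
                     probs = alpha),
      sim_hi = apply(sim_pct[, b, , drop = FALSE], 3, stats::quantile,
                     probs = 1 - alpha)
    )
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, n_sim = n_sim, seed = seed, breaks = br),
            class = "pcvpc")
}
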