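#' Maintenance dosing regimen
#'
#' A fixed dose given once every `interval_weeks` weeks for `n_cycles` cycles,
#' starting at `start_day`. One "cycle" is one dosing interval.
#'
#' @param dose_mg dose amount (mg), >= 0 (0 encodes a washout pseudo-regimen).
#' @param interval_weeks dosing interval (weeks), > 0.
#' @param n_cycles number of cycles, >= 1.
#' @param start_day time of the first dose (days).
#' @return object of class `regimen`.
#' @export
regimen <- function(dose_mg, interval_weeks, n_cycles = 5L, start_day = 0) {
  if (dose_mg < 0) stop("`dose_mg` must be >= 0", call. = FALSE)
  assert_positive(interval_weeks, "interval_weeks")
  stopifnot(n_cycles >= 1)
  structure(list(dose_mg = dose_mg, interval_weeks = interval_weeks,
                 n_cycles = as.integer(n_cycles), start_day = start_day),
            class = "regimen")
}

#' @export
format.regimen <- function(x, ...) sprintf("%g mg q%gw", x$dose_mg, x$interval_weeks)

#' @export
print.regimen <- function(x, ...) {
  cat(format(x), sprintf("(%d cycles from day %g)\n", x$n_cycles, x$start_day))
  invisible(x)
}

#' Dose events implied by a regimen
#'
#' @param reg a [regimen()].
#' @return data.frame with columns `time` (days) and `amt` (mg).
#' @export
regimen_doses <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  data.frame(
    time = reg$start_day + (seq_len(reg$n_cycles) - 1L) * weeks_to_days(reg$interval_weeks),
    amt = reg$dose_mg
  )
}

#' Dose intensity of a regimen (mg per week)
#'
#' The total order used to prefer "optimized" regimens: lower dose intensity
#' means less drug per unit time.
#'
#' @param reg a [regimen()].
#' @return mg/week.
#' @export
dose_intensity <- function(reg) reg$dose_mg / reg$interval_weeks

#' Candidate regimen grid
#'
#' Cross product of dose levels and dosing intervals; the default grid is the
#' 8 candidates 45/90 mg at q8w/q12w/q16w/q20w.
#'
#' @param doses dose levels (mg).
#' @param intervals dosing intervals (weeks).
#' @return list of [regimen()] objects, named by their label.
#' @export
regimen_grid <- function(doses = c(45, 90), intervals = c(8, 12, 16, 20)) {
  if (!length(doses) || !length(intervals)) {
    stop("candidate grid must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(dose = doses, interval = intervals)
  out <- lapply(seq_len(nrow(grid)),
                function(i) regimen(grid$dose[i], grid$interval[i]))
  names(out) <- vapply(out, format, character(1))
  out
}

#' Parse a regimen label like "45 mg q12w"
#'
#' @param label character vector of labels.
#' @return list of [regimen()] objects.
#' @export
parse_regimen <- function(label) {
  m <- regmatches(label, regexec("^([0-9.]+) ?mg q([0-9.]+)w$", label))
  lapply(m, function(g) {
    if (length(g) != 3) stop("unparseable regimen label", call. = FALSE)
    regimen(as.numeric(g[2]), as.numeric(g[3]))
  })
}
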