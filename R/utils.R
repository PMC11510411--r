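#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a per-subject random seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#'
#' @param master integer master seed.
#' @param id subject index (1-based) or other small positive integer.
#' @return an integer seed.
#' @export
derive_seed <- function(master, id) {
  as.integer((as.numeric(master) %% 1e6) * 1500 + as.numeric(id) %% 1500)
}

WEEK <- 7 # days per week, exact

weeks_to_days <- function(w) w * WEEK
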