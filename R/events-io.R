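EVENT_COLS <- c("ID", "TIME", "TYPE", "AMT", "DV", "CENS", "WT", "PASI0")
EVENT_TYPES <- c("dose", "pk", "pasi")

#' Write a cohort as a pharmacometric event-record CSV
#'
#' One row per event. Columns: `ID` (subject), `TIME` (days), `TYPE`
#' (`dose`/`pk`/`pasi`), `AMT` (mg, dose rows), `DV` (mg/L for `pk`, PASI for
#' `pasi`), `CENS` (0 quantified, 1 below 0.63 mg/L, 2 above 20 mg/L),
#' `WT` (kg), `PASI0` (observed baseline PASI). Concentrations are in mg/L,
#' numerically identical to the assay's ug/mL.
#'
#' @param cohort a `utk_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    rbind(
      data.frame(ID = p$id, TIME = p$doses$time, TYPE = "dose", AMT = p$doses$amt,
                 DV = NA_real_, CENS = NA_integer_, WT = p$weight, PASI0 = p$pasi0),
      if (nrow(p$pk_obs)) data.frame(ID = p$id, TIME = p$pk_obs$time, TYPE = "pk",
                                     AMT = NA_real_, DV = p$pk_obs$dv,
                                     CENS = p$pk_obs$cens, WT = p$weight,
                                     PASI0 = p$pasi0),
      if (nrow(p$pd_obs)) data.frame(ID = p$id, TIME = p$pd_obs$time, TYPE = "pasi",
                                     AMT = NA_real_, DV = p$pd_obs$dv,
                                     CENS = 0L, WT = p$weight, PASI0 = p$pasi0)
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$ID, df$TIME, match(df$TYPE, EVENT_TYPES)), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a pharmacometric event-record CSV
#'
#' Validates the header, types, units and record structure (see
#' [write_event_csv()] for the format), reporting every violation with its
#' row number, and assembles a cohort. The current regimen of each subject is
#' reconstructed from the dose records (modal amount and modal inter-dose
#' spacing).
#'
#' @param path CSV file.
#' @return a `utk_cohort` (without hidden truths).
#' @export
read_event_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), EVENT_COLS)
  missing <- setdiff(EVENT_COLS, names(df))
  if (length(extra) || length(missing)) {
    stop("invalid header; unknown: [", paste(extra, collapse = ", "),
         "], missing: [", paste(missing, collapse = ", "), "]", call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty event file: returning empty cohort")
    return(structure(list(), class = "utk_cohort"))
  }

  problems <- character(0)
  bad <- function(rows, msg) {
    if (length(rows)) problems <<- c(problems,
      sprintf("row %d: %s", rows + 1L, msg)) # +1 for header line
  }
  bad(which(!df$TYPE %in% EVENT_TYPES), "unknown TYPE")
  bad(which(!is.finite(df$TIME) | df$TIME < 0), "negative or missing TIME")
  bad(which(df$TYPE == "dose" & (!is.finite(df$AMT) | df$AMT < 0)),
      "dose with negative or missing AMT")
  bad(which(df$TYPE != "dose" & !is.finite(df$DV)), "observation with missing DV")
  bad(which(df$TYPE == "pasi" & is.finite(df$DV) & df$DV < 0), "negative PASI")
  bad(which(!is.finite(df$WT) | df$WT <= 0), "non-positive WT")
  bad(which(!is.finite(df$PASI0) | df$PASI0 <= 0), "non-positive PASI0")
  key <- paste(df$ID, df$TIME, df$TYPE)
  obs <- df$TYPE != "dose"
  bad(which(obs & duplicated(key)), "duplicate (ID, TIME, TYPE) record")
  if (length(problems)) {
    stop("event file validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  patients <- lapply(split(df, df$ID), function(d) {
    d <- d[order(d$TIME, match(d$TYPE, EVENT_TYPES)), ]
    doses <- d[d$TYPE == "dose", c("TIME", "AMT")]
    names(doses) <- c("time", "amt")
    rownames(doses) <- NULL
    pk <- d[d$TYPE == "pk", c("TIME", "DV", "CENS")]
    names(pk) <- c("time", "dv", "cens")
    pk$cens[is.na(pk$cens)] <- 0L
    rownames(pk) <- NULL
    pd <- d[d$TYPE == "pasi", c("TIME", "DV")]
    names(pd) <- c("time", "dv")
    rownames(pd) <- NULL
    reg <- if (nrow(doses) >= 2) {
      amt <- as.numeric(names(which.max(table(doses$amt))))
      gap <- as.numeric(names(which.max(table(round(diff(doses$time), 6)))))
      regimen(amt, gap / WEEK, n_cycles = nrow(doses), start_day = doses$time[1])
    } else if (nrow(doses) == 1) {
      regimen(doses$amt[1], 12, n_cycles = 1L, start_day = doses$time[1])
    } else NULL
    list(id = d$ID[1], weight = d$WT[1], pasi0 = d$PASI0[1], regimen = reg,
         doses = doses, pk_obs = pk, pd_obs = pd, truth = NULL)
  })
  ord <- order(vapply(patients, function(p) p$id, numeric(1)))
  structure(unname(patients[ord]), class = "utk_cohort")
}
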