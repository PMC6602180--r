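#' Read a NONMEM-dialect consolidation-cycle dataset
#'
#' Parses the nine-column dialect `ID TIME DV CMT AMT RATE DUR MDV EVID`
#' (missing fields as `.`): dose rows (`EVID = 1`) become infusion events
#' targeting the central PK compartment and must carry `AMT > 0`, `DUR > 0`
#' and `RATE = -2` (duration-specified infusion); observation rows
#' (`EVID = 0`) become WBC counts regardless of the declared observation
#' `CMT` index. Records are grouped by `ID`; `TIME` is taken relative to each
#' id's first record, and negative times are rejected.
#'
#' @param path CSV file path.
#' @param bsa Body surface area (m^2) attached to the reconstructed
#'   schedules (the dialect does not carry it); also used to infer the
#'   schedule label from the dose pattern.
#' @return A named list of [cycle_data()], one per `ID`.
#' @export
read_nonmem <- function(path, bsa = 1.78) {
  raw <- read.csv(path, na.strings = c(".", "NA", ""),
                  stringsAsFactors = FALSE)
  need <- c("ID", "TIME", "DV", "CMT", "AMT", "RATE", "DUR", "MDV", "EVID")
  if (!identical(sort(names(raw)), sort(need))) {
    extra <- setdiff(names(raw), need); miss <- setdiff(need, names(raw))
    abort(paste0("Unexpected dataset columns.",
                 if (length(miss)) paste0(" Missing: ", paste(miss, collapse = ", "), "."),
                 if (length(extra)) paste0(" Unknown: ", paste(extra, collapse = ", "), ".")))
  }
  raw <- raw[, need]
  bad_evid <- which(!raw$EVID %in% c(0, 1))
  if (length(bad_evid)) {
    abort(sprintf("EVID outside {0, 1} at row %d.", bad_evid[1]))
  }
  ids <- unique(raw$ID)
  out <- list()
  for (id in ids) {
    rows <- raw[raw$ID == id, ]
    t0 <- rows$TIME[1]
    rows$TIME <- rows$TIME - t0
    if (any(rows$TIME < 0)) {
      abort(sprintf("Negative relative time for ID %s.", id))
    }
    dose <- rows[rows$EVID == 1, ]
    obs <- rows[rows$EVID == 0, ]
    if (nrow(dose)) {
      bad <- which(is.na(dose$RATE) | dose$RATE != -2)
      if (length(bad)) {
        abort(sprintf("Dose row with RATE != -2 for ID %s (row %d).",
                      id, bad[1]))
      }
      if (any(is.na(dose$AMT) | dose$AMT <= 0) ||
          any(is.na(dose$DUR) | dose$DUR <= 0)) {
        abort(sprintf("Dose rows for ID %s need AMT > 0 and DUR > 0.", id))
      }
    }
    if (!nrow(obs)) abort(sprintf("No observation rows for ID %s.", id))
    if (any(is.na(obs$DV))) {
      abort(sprintf("Observation row with missing DV for ID %s.", id))
    }
    events <- tibble(start = dose$TIME, duration = dose$DUR,
                     amount = dose$AMT)
    sched <- infusion_schedule(events, bsa = bsa,
                               label = infer_schedule_label(events, bsa))
    out[[as.character(id)]] <- cycle_data(
      id = as.character(id),
      observations = tibble(time = obs$TIME, wbc = obs$DV),
      schedule = sched
    )
  }
  out
}

#' Write cycles as a NONMEM-dialect dataset
#'
#' Inverse of [read_nonmem()] on the supported dialect: one dose row per
#' infusion event (`EVID = 1`, `CMT = 1`, `RATE = -2`, `MDV = 1`) and one
#' observation row per WBC count (`EVID = 0`, `CMT = 5`, `MDV = 0`), ordered
#' by id and time with dose rows first at ties; missing fields written as
#' `.`. A write -> read -> write round trip is byte-identical.
#'
#' @param cycles A list of [cycle_data()] (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nonmem <- function(cycles, path) {
  if (inherits(cycles, "cycle_data")) cycles <- list(cycles)
  fmt <- function(x) ifelse(is.na(x), ".", sprintf("%.10g", x))
  rows <- purrr::map_dfr(cycles, function(cy) {
    ev <- as.data.frame(cy$schedule)
    obs <- cy$observations
    dose <- if (nrow(ev)) {
      tibble(ID = as.character(cy$id), TIME = ev$start, DV = NA_real_,
             CMT = 1, AMT = ev$amount, RATE = -2, DUR = ev$duration,
             MDV = 1, EVID = 1)
    } else NULL
    obs_rows <- tibble(ID = as.character(cy$id), TIME = obs$time,
                       DV = obs$wbc, CMT = 5, AMT = NA_real_,
                       RATE = NA_real_, DUR = NA_real_, MDV = 0, EVID = 0)
    all <- dplyr::bind_rows(dose, obs_rows)
    all[order(all$TIME, all$EVID != 1), ]
  })
  txt <- vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$ID[i], fmt(rows$TIME[i]), fmt(rows$DV[i]), rows$CMT[i],
          fmt(rows$AMT[i]), fmt(rows$RATE[i]), fmt(rows$DUR[i]),
          rows$MDV[i], rows$EVID[i], sep = ",")
  }, character(1))
  writeLines(c("ID,TIME,DV,CMT,AMT,RATE,DUR,MDV,EVID", txt), path)
  invisible(path)
}
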