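#' Consolidation-cycle data
#'
#' One consolidation cycle's WBC observations and dosing events -- the unit
#' of personalisation. Observation times are days from cycle start; WBC
#' counts are in G/L and must be positive (fitting uses log residuals).
#'
#' @param id Cycle identifier.
#' @param observations Data frame with columns `time` (days) and `wbc` (G/L).
#' @param schedule An [infusion_schedule()] with the cycle's dosing events.
#' @param patient_id Patient identifier (defaults to `id`).
#' @return An object of class `cycle_data`.
#' @export
cycle_data <- function(id, observations, schedule, patient_id = id) {
  obs <- as_tibble(observations)[, c("time", "wbc")]
  if (nrow(obs) == 0) abort("A cycle needs at least one observation.")
  if (any(obs$wbc <= 0)) abort("WBC observations must be > 0 G/L.")
  if (any(obs$time < 0)) abort("Observation times must be >= 0.")
  obs <- obs[order(obs$time), ]
  stopifnot(inherits(schedule, "infusion_schedule"))
  structure(list(id = id, patient_id = patient_id, observations = obs,
                 schedule = schedule),
            class = "cycle_data")
}

#' @export
print.cycle_data <- function(x, ...) {
  cat(sprintf("<cycle_data> %s (patient %s): %d WBC counts over %.1f d, schedule %s\n",
              x$id, x$patient_id, nrow(x$observations),
              max(x$observations$time), attr(x$schedule, "label")))
  invisible(x)
}

## Horizon that safely covers a cycle's observations and dosing.
cycle_horizon <- function(cycle) {
  ev <- as.data.frame(cycle$schedule)
  max(cycle$observations$time,
      if (nrow(ev)) max(ev$start + ev$duration) else 0) + 1e-6
}
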