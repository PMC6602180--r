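#' Schedule-discrimination study across personalised models
#'
#' Simulates every personalised model (PM) under each candidate schedule
#' (starting from its fitted steady state) and summarises the recovery
#' statistics per model x schedule. A personalised *cycle* is excluded
#' entirely when at least one of its predictions -- any model, any schedule
#' -- produces no WBC count below the threshold, so recovery-time medians
#' are never computed against absent leukopenia episodes.
#'
#' @param pms List of `myelo_fit` objects (typically one per cycle per
#'   candidate model, all personalised on their actual schedules).
#' @param schedules Character vector of schedule labels to predict
#'   (default `c("D123", "D135")`).
#' @param threshold Leukopenia threshold (G/L).
#' @param horizon Simulation horizon per prediction (days).
#' @param grid_by Output grid spacing (days).
#' @return An object of class `discrimination_report`: `per_pm` (one row per
#'   PM x schedule with recovery stats), `stats` (median/sd/min/max per model
#'   x schedule over included PMs), `differences` (per-model median and sd of
#'   the within-PM t_rec difference between the last and first schedule,
#'   e.g. D135 - D123), `included`, `excluded` (cycle ids).
#' @export
discrimination_study <- function(pms, schedules = c("D123", "D135"),
                                 threshold = 1, horizon = 60,
                                 grid_by = 0.05) {
  if (!length(pms)) abort("No personalised models supplied.")
  per_pm <- purrr::map_dfr(pms, function(fit) {
    stopifnot(inherits(fit, "myelo_fit"))
    cy <- fit$problem$cycles[[1]]
    bsa <- attr(cy$schedule, "bsa")
    purrr::map_dfr(schedules, function(lab) {
      traj <- predict_cycle(fit, schedule = build_schedule(lab, bsa = bsa),
                            horizon = horizon,
                            times = seq(0, horizon, by = grid_by),
                            init = "steady")
      st <- recovery_stats(traj, threshold = threshold)
      tibble(cycle = cy$id, model = fit$problem$spec$id, schedule = lab,
             t_rec = st$t_rec, t_leu = st$t_leu, nadir = st$nadir)
    })
  })
  excl <- unique(per_pm$cycle[is.na(per_pm$t_rec)])
  incl <- setdiff(unique(per_pm$cycle), excl)
  if (!length(incl)) abort("All personalised cycles were excluded.")
  kept <- dplyr::filter(per_pm, .data$cycle %in% incl)
  stats <- kept |>
    dplyr::group_by(.data$model, .data$schedule) |>
    dplyr::summarise(dplyr::across(
      c("t_rec", "t_leu", "nadir"),
      list(median = median, sd = sd, min = min, max = max)
    ), n = dplyr::n(), .groups = "drop")
  ref <- schedules[1]; alt <- schedules[length(schedules)]
  differences <- kept |>
    dplyr::filter(.data$schedule %in% c(ref, alt)) |>
    tidyr::pivot_wider(id_cols = c("cycle", "model"),
                       names_from = "schedule", values_from = "t_rec") |>
    dplyr::mutate(diff = .data[[alt]] - .data[[ref]]) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(t_rec_diff_median = median(.data$diff),
                     t_rec_diff_sd = sd(.data$diff), .groups = "drop")
  structure(list(per_pm = per_pm, stats = stats, differences = differences,
                 included = incl, excluded = excl,
                 schedules = schedules, threshold = threshold),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %d included / %d excluded cycles; schedules %s\n",
              length(x$included), length(x$excluded),
              paste(x$schedules, collapse = ", ")))
  print(x$differences)
  invisible(x)
}

#' Treatment-timing study: nadir versus cycle start shift
#'
#' Translates the dosing block of a personalised cycle day by day (default
#' -10 ... +10, excluding 0) and records the nadir of each simulated
#' trajectory. The dosing block sits behind a pad of drug-free days so that
#' negative shifts stay inside the horizon; the WBC state starts at the
#' fitted initial conditions and evolves drug-free until dosing begins.
#'
#' @param fit A `myelo_fit`.
#' @param shifts Integer day shifts (default `c(-10:-1, 1:10)`).
#' @param cycle_index Which fitted cycle to translate (default: last).
#' @param pad Drug-free lead time (days) before the nominal dosing start;
#'   must be >= `-min(shifts)`.
#' @param horizon Simulation horizon beyond the padded dosing block.
#' @param grid_by Output grid spacing (days).
#' @return A tibble of class `timing_study` with columns `shift` and `nadir`
#'   (G/L); attributes `nominal_nadir` (unshifted simulation) and
#'   `observed_nadir` (minimum measured count of that cycle).
#' @export
timing_study <- function(fit, shifts = c(-10:-1, 1:10),
                         cycle_index = NULL, pad = 10, horizon = 40,
                         grid_by = 0.05) {
  stopifnot(inherits(fit, "myelo_fit"))
  cycle_index <- cycle_index %||% length(fit$problem$cycles)
  cy <- fit$problem$cycles[[cycle_index]]
  par <- fit$params[[cycle_index]]
  problem <- fit$problem
  if (pad + min(shifts) < 0) {
    abort("Shift pushes dosing before the simulation origin; increase `pad`.")
  }
  y0 <- initial_state(problem$spec, par, problem$consts)
  nadir_for <- function(shift) {
    sched <- shift_schedule(cy$schedule, pad + shift)
    end <- max(sched$start + sched$duration)
    h <- end + horizon
    traj <- simulate_wbc(problem$spec, par, problem$consts, problem$pk,
                         sched, horizon = h,
                         times = seq(0, h, by = grid_by), init = y0)
    min(traj$wbc[traj$time >= min(sched$start)])
  }
  out <- tibble(shift = sort(shifts),
                nadir = vapply(sort(shifts), nadir_for, numeric(1)))
  structure(out, class = c("timing_study", class(out)),
            nominal_nadir = nadir_for(0),
            observed_nadir = min(cy$observations$wbc))
}

#' Inter-individual PK variability study
#'
#' Propagates lognormal inter-individual variability (IIV) on clearance and
#' central volume through the WBC models: per draw, `CL` and `Vc` are drawn
#' lognormally at the given coefficients of variation (median preserved,
#' `sdlog = sqrt(log(1 + CV^2))`), the micro rate constants are re-derived
#' with `Q` and `Vp` fixed, the unit constant `c_V` is re-derived from the
#' drawn `Vc`, and each model x schedule combination is simulated from the
#' steady state with fixed PD parameters.
#'
#' @param params A [pd_params()] set of fixed population PD parameters.
#' @param pk Base [pk_params()] supplying the median `CL`, `Q`, `Vc`, `Vp`.
#' @param models Character vector of model ids; each is used with the I1
#'   (steady-state) initial condition.
#' @param schedules Schedule labels to compare.
#' @param cv_cl,cv_vc Coefficients of variation for `CL` and `Vc`.
#' @param n Number of draws per model x schedule.
#' @param seed RNG seed.
#' @param bsa Body surface area for the schedules (m^2).
#' @param threshold Leukopenia threshold (G/L).
#' @param horizon Simulation horizon (days).
#' @param grid_by Output grid spacing (days).
#' @param k_ma,mm_cyt Constants passed to [model_constants()] per draw.
#' @return A tibble with one row per draw x model x schedule: `model`,
#'   `schedule`, `draw`, `cl`, `vc`, `t_rec`, `t_leu`, `nadir`. Failed
#'   simulations are dropped (attribute `n_failed`).
#' @export
iiv_study <- function(params, pk = pk_params_arac(),
                      models = c("M3", "M10"),
                      schedules = c("D123", "D135"),
                      cv_cl = 0.45, cv_vc = 0.70, n = 500, seed = 1,
                      bsa = 1.78, threshold = 1, horizon = 60,
                      grid_by = 0.1, k_ma = 24 * log(2) / 7,
                      mm_cyt = 243.22) {
  stopifnot(inherits(params, "pd_params"))
  macro <- micro_to_macro(pk)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  sdl_cl <- sqrt(log(1 + cv_cl^2)); sdl_vc <- sqrt(log(1 + cv_vc^2))
  cls <- rlnorm(n, meanlog = log(macro["cl"]), sdlog = sdl_cl)
  vcs <- rlnorm(n, meanlog = log(macro["vc"]), sdlog = sdl_vc)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  n_failed <- 0L
  scheds <- lapply(schedules, build_schedule, bsa = bsa)
  names(scheds) <- schedules
  rows <- list()
  for (i in seq_len(n)) {
    pk_i <- macro_to_micro(cl = cls[i], q = unname(macro["q"]),
                           vc = vcs[i], vp = unname(macro["vp"]))
    consts_i <- model_constants(vc = vcs[i], k_ma = k_ma, mm_cyt = mm_cyt)
    for (m in models) {
      spec <- model_spec(m, init = "I1")
      for (lab in schedules) {
        st <- tryCatch({
          traj <- simulate_wbc(spec, params, consts_i, pk_i, scheds[[lab]],
                               horizon = horizon,
                               times = seq(0, horizon, by = grid_by))
          recovery_stats(traj, threshold = threshold)
        }, error = function(e) NULL)
        if (is.null(st)) { n_failed <- n_failed + 1L; next }
        rows[[length(rows) + 1]] <-
          tibble(model = m, schedule = lab, draw = i,
                 cl = cls[i], vc = vcs[i],
                 t_rec = st$t_rec, t_leu = st$t_leu, nadir = st$nadir)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- n_failed
  out
}
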