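#' Specification of a synthetic consolidation cohort
#'
#' Describes the statistical structure of a synthetic WBC cohort: patient
#' count, the distribution of consecutive cycles per patient (1-3, default
#' proportions 9:9:5), the schedule mix (default D135/d135/D123/D12 in
#' proportions 23:15:2:2, assigned per patient), the median and
#' coefficient of variation of the true personalised parameters, the
#' multiplicative lognormal measurement-noise level, the almost-daily
#' sampling grid with dropout, and the BSA distribution. Between-cycle
#' carry-over is emulated by drawing each cycle's initial circulating count
#' as `B0 = B * lognormal(CV = carryover_cv)`.
#'
#' The default medians are a nominal patient calibrated so that the truth
#' model (M10) under D135 shows the clinically familiar picture: nadir well
#' below 1 G/L around the end of week two and recovery above 1 G/L in the
#' early twenties of days.
#'
#' @param n_patients Number of patients.
#' @param cycle_prob Probabilities of 1, 2, 3 cycles per patient.
#' @param schedule_prob Named probabilities over schedule labels.
#' @param medians Named vector of median true parameters (`B`, `slope`,
#'   `k_tr`, `gamma`).
#' @param cv Named vector of lognormal CVs for the same parameters.
#' @param carryover_cv CV of the per-cycle initial circulating count around
#'   `B`.
#' @param sigma_log Multiplicative measurement noise (sd of log counts).
#' @param dropout Probability that a scheduled daily sample is missing.
#' @param cycle_days Range (min, max) of cycle observation spans in days.
#' @param bsa_mean,bsa_sd Normal BSA distribution (m^2), truncated at 1.2.
#' @param seed Cohort seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 23,
                        cycle_prob = c(9, 9, 5) / 23,
                        schedule_prob = c(D135 = 23, d135 = 15,
                                          D123 = 2, D12 = 2) / 42,
                        medians = c(B = 5.5, slope = 5.2, k_tr = 0.19,
                                    gamma = 0.45),
                        cv = c(B = 0.25, slope = 0.25, k_tr = 0.2,
                               gamma = 0.25),
                        carryover_cv = 0.2,
                        sigma_log = 0.15, dropout = 0.1,
                        cycle_days = c(25, 32),
                        bsa_mean = 1.78, bsa_sd = 0.15, seed = 1) {
  stopifnot(abs(sum(cycle_prob) - 1) < 1e-8,
            abs(sum(schedule_prob) - 1) < 1e-8,
            all(medians > 0), all(cv >= 0), sigma_log >= 0,
            dropout >= 0 && dropout < 1)
  structure(list(n_patients = n_patients, cycle_prob = cycle_prob,
                 schedule_prob = schedule_prob, medians = medians, cv = cv,
                 carryover_cv = carryover_cv, sigma_log = sigma_log,
                 dropout = dropout, cycle_days = cycle_days,
                 bsa_mean = bsa_mean, bsa_sd = bsa_sd, seed = seed),
            class = "cohort_spec")
}

## Lognormal with preserved median and given CV.
rlnorm_cv <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  rlnorm(n, meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

#' Draw true patient-level parameters for a synthetic cohort
#'
#' Samples per-patient true parameters (lognormal around the spec medians,
#' redrawn until inside the personalisation bounds), BSA, schedule label and
#' cycle count. Reproducible under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: `patient_id`, `B`, `slope`,
#'   `k_tr`, `gamma`, `bsa`, `schedule`, `n_cycles`.
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  bb <- default_fit_bounds()
  draw_par <- function(name) {
    x <- rlnorm_cv(spec$n_patients, spec$medians[[name]], spec$cv[[name]])
    b <- bb[[name]]
    bad <- x < b[1] | x > b[2]
    while (any(bad)) {
      x[bad] <- rlnorm_cv(sum(bad), spec$medians[[name]], spec$cv[[name]])
      bad <- x < b[1] | x > b[2]
    }
    x
  }
  out <- tibble(
    patient_id = sprintf("P%02d", seq_len(spec$n_patients)),
    B = draw_par("B"), slope = draw_par("slope"),
    k_tr = draw_par("k_tr"), gamma = draw_par("gamma"),
    bsa = pmax(rnorm(spec$n_patients, spec$bsa_mean, spec$bsa_sd), 1.2),
    schedule = sample(names(spec$schedule_prob), spec$n_patients,
                      replace = TRUE, prob = spec$schedule_prob),
    n_cycles = sample(seq_along(spec$cycle_prob), spec$n_patients,
                      replace = TRUE, prob = spec$cycle_prob)
  )
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out
}

#' Simulate a synthetic consolidation cohort
#'
#' Generates cycle-level WBC datasets with the structure of clinical
#' consolidation-cycle data: per patient, true parameters are drawn via
#' [sample_parameters()]; each cycle is simulated under the patient's
#' schedule from a carry-over initial state (`B0` around `B`), sampled on an
#' almost-daily grid with dropout, and observed under multiplicative
#' lognormal noise (counts stay strictly positive). Cycles whose simulation
#' fails are regenerated with a fresh sub-seed.
#'
#' @param spec A [cohort_spec()].
#' @param model Truth [model_spec()] (default M10).
#' @param pk [pk_params()] used for the drug forcing.
#' @param consts Optional [model_constants()].
#' @return A named list of [cycle_data()] (ids `P01_C1`, ...), with
#'   attributes `truth` (tibble of per-cycle true parameters) and `spec`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 2, seed = 42))
#' cohort[[1]]
#' @export
simulate_cohort <- function(spec, model = model_spec("M10"),
                            pk = pk_params_arac(), consts = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "model_spec"))
  consts <- consts %||% model_constants(vc = pk$vc)
  pats <- sample_parameters(spec)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed + 1L)
  cycles <- list()
  truth <- list()
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    for (cc in seq_len(p$n_cycles)) {
      for (attempt in 1:5) {
        ndays <- sample(seq(spec$cycle_days[1], spec$cycle_days[2]), 1)
        b0 <- p$B * rlnorm_cv(1, 1, spec$carryover_cv)
        bbm <- p$B * consts$k_ma / p$k_tr
        par <- pd_params(B = p$B, slope = p$slope, k_tr = p$k_tr,
                         gamma = p$gamma, B0 = b0, xpr0 = bbm, xtr0 = bbm)
        sched <- build_schedule(p$schedule, bsa = p$bsa)
        days <- 0:ndays
        keep <- c(TRUE, rbinom(ndays, 1, 1 - spec$dropout) == 1)
        times <- days[keep]
        traj <- tryCatch(
          simulate_wbc(model, par, consts, pk, sched,
                       horizon = ndays + 1e-6, times = times),
          error = function(e) NULL
        )
        if (!is.null(traj)) break
      }
      if (is.null(traj)) abort("Cohort cycle simulation failed repeatedly.")
      wbc <- pmax(traj$wbc, 1e-3) *
        exp(rnorm(length(times), 0, spec$sigma_log))
      id <- sprintf("%s_C%d", p$patient_id, cc)
      cycles[[id]] <- cycle_data(
        id = id, patient_id = p$patient_id,
        observations = tibble(time = times, wbc = wbc),
        schedule = sched
      )
      truth[[id]] <- tibble(cycle = id, patient_id = p$patient_id,
                            cycle_no = cc, B = p$B, slope = p$slope,
                            k_tr = p$k_tr, gamma = p$gamma, B0 = b0,
                            schedule = p$schedule, bsa = p$bsa,
                            n_days = ndays)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(cycles, truth = dplyr::bind_rows(truth), spec = spec,
            model_id = model$id)
}

#' Generate synthetic Ara-C concentration records
#'
#' Samples the exact PK solution at the given times and applies the
#' exponential error model `conc = (x1/Vc) * exp(sigma_log * z)`,
#' `z ~ N(0, 1)`.
#'
#' @param pk A [pk_params()].
#' @param schedule An [infusion_schedule()].
#' @param sample_times Sampling times (days).
#' @param sigma_log Log-scale noise sd (0 for noise-free records).
#' @param seed Optional RNG seed.
#' @return A tibble with `time` (days) and `conc` (mg/L).
#' @export
gen_pk_concentration_data <- function(pk, schedule, sample_times,
                                      sigma_log = 0.2, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  sim <- simulate_pk(pk, schedule, sort(sample_times))
  tibble(time = sim$time,
         conc = sim$conc * exp(rnorm(nrow(sim), 0, sigma_log)))
}

#' Kern-style high-dose PK sampling design
#'
#' The regimen under which the published high-dose Ara-C concentration data
#' were collected: 3 g/m^2 infusions over 3 h every 12 h on days 1, 2, 8 and
#' 9 (BSA 1.78 m^2), with concentration sampling on days 1 and 8.
#' `kern_sampling_times()` returns 86 sampling times (43 per sampled day,
#' spread over the 12 h following the first infusion start of the day).
#'
#' @param bsa Body surface area (m^2).
#' @return `kern_sampling_schedule()`: an [infusion_schedule()];
#'   `kern_sampling_times()`: numeric vector of 86 times (days).
#' @export
kern_sampling_schedule <- function(bsa = 1.78) {
  starts <- c(0, 0.5, 1, 1.5, 7, 7.5, 8, 8.5)
  infusion_schedule(
    tibble(start = starts, duration = 0.125, amount = 3000 * bsa),
    bsa = bsa, label = "kern-q12h-d1289"
  )
}

#' @rdname kern_sampling_schedule
#' @export
kern_sampling_times <- function() {
  offsets_h <- seq(0.25, 11, length.out = 43)
  sort(c(offsets_h / 24, 7 + offsets_h / 24))
}
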