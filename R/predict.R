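#' Simulate a fitted model under a (possibly new) schedule
#'
#' Simulates a personalised model forward. By default the WBC compartments
#' start at the fitted steady state (`x_pr = x_tr = B_bm`, `x_ma = B`), the
#' natural choice when predicting a cycle whose observations were not used
#' for fitting; `init = "fitted"` uses the fitted initial-state parameters of
#' cycle `cycle_index` instead.
#'
#' @param fit A `myelo_fit`.
#' @param schedule An [infusion_schedule()]; defaults to the schedule of
#'   cycle `cycle_index`.
#' @param horizon Simulation horizon (days).
#' @param times Optional output grid.
#' @param init `"steady"` (default) or `"fitted"`.
#' @param cycle_index Which fitted cycle supplies schedule/initial state.
#' @return A `wbc_trajectory` tibble.
#' @export
predict_cycle <- function(fit, schedule = NULL, horizon = 28, times = NULL,
                          init = c("steady", "fitted"), cycle_index = 1) {
  stopifnot(inherits(fit, "myelo_fit"))
  init <- match.arg(init)
  problem <- fit$problem
  par <- fit$params[[cycle_index]]
  schedule <- schedule %||% problem$cycles[[cycle_index]]$schedule
  spec <- problem$spec
  y0 <- if (init == "steady") {
    bbm <- b_bm(par, problem$consts)
    setNames(c(bbm, rep(bbm, spec$n_tr), par$B),
             c("xpr", paste0("xtr", seq_len(spec$n_tr)), "xma"))
  } else {
    initial_state(spec, par, problem$consts)
  }
  simulate_wbc(spec, par, problem$consts, problem$pk, schedule,
               horizon = horizon, times = times, init = y0)
}

#' Cross-validated prediction of a patient's last cycle
#'
#' Fits the model to all but the last of a patient's cycles and predicts the
#' held-out last cycle under its actual dosing schedule; the held-out
#' observations are never seen by the fit. The prediction starts from the
#' fitted steady state.
#'
#' @param cycles Ordered list of [cycle_data()] for one patient (>= 2).
#' @inheritParams fit_cycle
#' @param horizon Prediction horizon; defaults to the held-out cycle's span.
#' @return An object of class `cycle_prediction`: `fit` (training fit),
#'   `cycle` (held-out cycle), `trajectory`, `fitted` (observed vs predicted
#'   on the held-out observation times) and `rmse` (G/L).
#' @export
cross_validate_last_cycle <- function(cycles, spec,
                                      consts = model_constants(),
                                      pk = pk_params_arac(),
                                      alpha = 1 / 2500,
                                      scale = c("log", "linear"),
                                      n_starts = 20, seed = 1,
                                      bounds = NULL, horizon = NULL) {
  if (length(cycles) < 2) abort("Cross-validation needs at least two cycles.")
  test <- cycles[[length(cycles)]]
  train <- cycles[-length(cycles)]
  fit <- fit_patient(train, spec, consts = consts, pk = pk, alpha = alpha,
                     scale = scale, n_starts = n_starts, seed = seed,
                     bounds = bounds)
  horizon <- horizon %||% cycle_horizon(test)
  obs_t <- sort(unique(test$observations$time))
  times <- sort(unique(c(seq(0, horizon, by = 0.05), obs_t)))
  traj <- predict_cycle(fit, schedule = test$schedule, horizon = horizon,
                        times = times, init = "steady")
  pred <- traj$wbc[match(test$observations$time, traj$time)]
  fitted <- tibble(cycle = test$id, time = test$observations$time,
                   observed = test$observations$wbc, predicted = pred)
  structure(list(fit = fit, cycle = test, trajectory = traj,
                 fitted = fitted,
                 rmse = sqrt(mean((pred - fitted$observed)^2))),
            class = "cycle_prediction")
}

#' @export
print.cycle_prediction <- function(x, ...) {
  cat(sprintf("<cycle_prediction> held-out cycle %s: RMSE %.3f G/L on %d observations\n",
              x$cycle$id, x$rmse, nrow(x$fitted)))
  invisible(x)
}

## Eigenvalue clipping to the nearest positive-semidefinite matrix.
nearest_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (all(e$values >= 0)) return((m + t(m)) / 2)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
  dimnames(out) <- dimnames(m)
  out
}

#' Monte-Carlo parameter-uncertainty band for a fitted model
#'
#' Propagates estimation uncertainty through the model: `n` parameter
#' vectors are drawn from the multivariate normal at (estimate, covariance),
#' draws outside the positivity/box bounds are resampled (up to 100 attempts
#' each, never clipped), each draw is simulated, and pointwise quantiles of
#' the simulated WBC are returned.
#'
#' @param fit A `myelo_fit` with a non-singular covariance (a
#'   non-positive-semidefinite covariance is repaired by eigenvalue clipping
#'   and a warning).
#' @param schedule Schedule to simulate (default: the fitted cycle's).
#' @param n Number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @param horizon Simulation horizon (days).
#' @param times Output grid (default 0.25-day spacing).
#' @param probs Quantile levels (must be sorted).
#' @param cycle_index Which fitted cycle's schedule/initial state to use.
#' @param init Initial-state handling, as in [predict_cycle()].
#' @return A tibble of class `uncertainty_band` with `time`, one quantile
#'   column per level (`q2.5`, `q50`, `q97.5` by default) and the nominal
#'   trajectory in `nominal`. Attribute `n_resampled` counts redraws.
#' @export
monte_carlo_band <- function(fit, schedule = NULL, n = 1000, seed = 1,
                             horizon = 28, times = NULL,
                             probs = c(0.025, 0.5, 0.975),
                             cycle_index = 1,
                             init = c("fitted", "steady")) {
  stopifnot(inherits(fit, "myelo_fit"))
  init <- match.arg(init)
  if (fit$singular || anyNA(fit$covariance)) {
    abort("Covariance unavailable or singular; cannot draw parameters.")
  }
  if (is.unsorted(probs, strictly = TRUE)) abort("`probs` must be sorted.")
  problem <- fit$problem
  times <- times %||% seq(0, horizon, by = 0.25)
  schedule <- schedule %||% problem$cycles[[cycle_index]]$schedule

  cov <- fit$covariance
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    warn("Covariance repaired to nearest positive-semidefinite matrix.")
    cov <- nearest_psd(cov)
  }
  mu <- fit$estimates
  p <- length(mu)

  simulate_theta <- function(theta) {
    par <- theta_to_params(problem, theta, cycle_index)
    y0 <- if (init == "fitted") initial_state(problem$spec, par, problem$consts)
          else {
            bbm <- b_bm(par, problem$consts)
            c(bbm, rep(bbm, problem$spec$n_tr), par$B)
          }
    simulate_wbc(problem$spec, par, problem$consts, problem$pk, schedule,
                 horizon = max(horizon, max(times)), times = times,
                 init = y0)$wbc
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n_resampled <- 0L
  draws <- matrix(NA_real_, nrow = n, ncol = p,
                  dimnames = list(NULL, names(mu)))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      th <- as.numeric(MASS::mvrnorm(1, mu, cov))
      if (all(th >= problem$lower) && all(th <= problem$upper)) {
        ok <- TRUE; break
      }
      n_resampled <- n_resampled + 1L
    }
    if (!ok) th <- as.numeric(mu) # fall back to the estimate, counted above
    draws[i, ] <- th
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  sims <- matrix(NA_real_, nrow = n, ncol = length(times))
  for (i in seq_len(n)) {
    sims[i, ] <- tryCatch(
      simulate_theta(setNames(draws[i, ], names(mu))),
      error = function(e) rep(NA_real_, length(times))
    )
  }
  qs <- apply(sims, 2, quantile, probs = probs, na.rm = TRUE)
  out <- tibble(time = times)
  for (k in seq_along(probs)) {
    out[[paste0("q", probs[k] * 100)]] <- qs[k, ]
  }
  out$nominal <- simulate_theta(mu)
  structure(out, class = c("uncertainty_band", class(out)),
            n_samples = n, probs = probs, n_resampled = n_resampled,
            n_failed = sum(is.na(sims[, 1])))
}
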