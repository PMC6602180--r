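#' Default parameter bounds for personalisation
#'
#' Box constraints used by the multistart least-squares personalisation.
#' They bracket published Friberg-type estimates with a wide margin. The
#' initial-state box for I3 is `[1e-3, 10 * B_bm]` with `B_bm` evaluated at
#' the data-informed starting point.
#'
#' @return Named list of `c(lower, upper)` pairs for `B` (G/L), `slope`,
#'   `k_tr` (1/day) and `gamma`.
#' @export
default_fit_bounds <- function() {
  list(B = c(1, 20), slope = c(1e-3, 10),
       k_tr = c(0.01, 5), gamma = c(0.01, 10))
}

## Build the estimation problem: free-parameter names, bounds, and the
## data-informed starting point. Initial-state parameters (I2/I3) are
## per-cycle.
fit_problem <- function(cycles, spec, consts, pk, alpha = 1 / 2500,
                        scale = c("log", "linear"), bounds = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(cycles, "cycle_data")) cycles <- list(cycles)
  if (!length(cycles)) abort("At least one cycle is required.")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  bb <- bounds %||% default_fit_bounds()
  nc <- length(cycles)
  suffix <- function(base) {
    if (nc == 1) base else as.vector(outer(base, seq_len(nc), paste, sep = "."))
  }
  par_names <- c("B", "slope", "k_tr", "gamma")
  if (spec$init %in% c("I2", "I3")) par_names <- c(par_names, suffix("B0"))
  if (spec$init == "I3") par_names <- c(par_names, suffix(c("xpr0", "xtr0")))

  # data-informed start
  first_obs <- vapply(cycles, function(cy) cy$observations$wbc[1], numeric(1))
  all_wbc <- unlist(lapply(cycles, function(cy) cy$observations$wbc))
  clamp <- function(x, b) pmin(pmax(x, b[1] * 1.0001), b[2] * 0.9999)
  B0s <- clamp(first_obs, bb$B)
  start <- c(B = clamp(unname(quantile(all_wbc, 0.75)), bb$B),
             slope = 2, k_tr = 0.1875, gamma = 0.5)
  bbm_start <- start[["B"]] * consts$k_ma / start[["k_tr"]]
  if (spec$init %in% c("I2", "I3")) {
    start <- c(start, setNames(B0s, suffix("B0")))
  }
  if (spec$init == "I3") {
    start <- c(start, setNames(rep(bbm_start, nc), suffix("xpr0")),
               setNames(rep(bbm_start, nc), suffix("xtr0")))
  }
  lower <- c(B = bb$B[1], slope = bb$slope[1], k_tr = bb$k_tr[1],
             gamma = bb$gamma[1])
  upper <- c(B = bb$B[2], slope = bb$slope[2], k_tr = bb$k_tr[2],
             gamma = bb$gamma[2])
  extra <- setdiff(par_names, names(lower))
  lower <- c(lower, setNames(rep(1e-3, length(extra)), extra))
  ub_extra <- ifelse(grepl("^B0", extra), bb$B[2], 10 * bbm_start)
  upper <- c(upper, setNames(ub_extra, extra))
  structure(list(cycles = cycles, spec = spec, consts = consts, pk = pk,
                 alpha = alpha, scale = scale, par_names = par_names,
                 start = start[par_names], lower = lower[par_names],
                 upper = upper[par_names]),
            class = "fit_problem")
}

## Parameters of cycle `i` from the free-parameter vector.
theta_to_params <- function(problem, theta, i) {
  nc <- length(problem$cycles)
  pick <- function(base) {
    nm <- if (nc == 1) base else paste(base, i, sep = ".")
    if (nm %in% names(theta)) unname(theta[nm]) else NULL
  }
  pd_params(B = unname(theta["B"]), slope = unname(theta["slope"]),
            k_tr = unname(theta["k_tr"]), gamma = unname(theta["gamma"]),
            B0 = pick("B0"), xpr0 = pick("xpr0"), xtr0 = pick("xtr0"))
}

#' Residual vector of a personalisation problem
#'
#' Stacks, for every cycle, the data residuals on the fitting scale
#' (log(predicted) - log(observed) by default) followed by the steady-state
#' penalty rows `sqrt(alpha) (xpr0 - B_bm)` and `sqrt(alpha) (xtr0 - B_bm)`
#' for the I3 initial-condition strategy. `B0` is never penalised.
#'
#' @param problem Internal problem object as assembled by [fit_cycle()]/
#'   [fit_patient()] (see details there); built from cycles, model spec,
#'   constants and PK parameters.
#' @param theta Named parameter vector on the natural scale.
#' @return Numeric residual vector; attribute `failed` flags simulation
#'   failure (large-residual fallback).
#' @keywords internal
#' @export
residual_vector <- function(problem, theta) {
  res <- numeric(0)
  failed <- FALSE
  for (i in seq_along(problem$cycles)) {
    cy <- problem$cycles[[i]]
    par <- theta_to_params(problem, theta, i)
    obs <- cy$observations
    sim_t <- sort(unique(c(0, obs$time)))
    traj <- tryCatch(
      simulate_wbc(problem$spec, par, problem$consts, problem$pk,
                   cy$schedule, horizon = cycle_horizon(cy), times = sim_t),
      error = function(e) NULL
    )
    if (is.null(traj)) {
      res <- c(res, rep(1e3, nrow(obs)))
      failed <- TRUE
    } else {
      pred <- traj$wbc[match(obs$time, traj$time)]
      pred <- pmax(pred, 1e-8)
      r <- if (problem$scale == "log") log(pred) - log(obs$wbc)
           else pred - obs$wbc
      res <- c(res, r)
    }
    if (problem$spec$init == "I3" && problem$alpha > 0) {
      bbm <- b_bm(par, problem$consts)
      sa <- sqrt(problem$alpha)
      res <- c(res, sa * (par$xpr0 - bbm),
               sa * sqrt(problem$spec$n_tr) * (par$xtr0 - bbm))
    }
  }
  attr(res, "failed") <- failed
  res
}

## Multistart Levenberg-Marquardt on log-parameters.
fit_optimise <- function(problem, n_starts = 20, seed = 1,
                         maxiter = 100) {
  rf_log <- function(lt) {
    r <- residual_vector(problem, setNames(exp(lt), problem$par_names))
    as.numeric(r)
  }
  lo <- log(problem$lower); up <- log(problem$upper)
  starts <- list(log(problem$start))
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (k in seq_len(n_starts - 1)) {
      # log-uniform around the data-informed start, clipped to bounds
      jitter <- runif(length(lo), -log(10), log(10))
      starts[[k + 1]] <- pmin(pmax(log(problem$start) + jitter, lo), up)
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  }
  best <- NULL
  diagnostics <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = rf_log, lower = lo, upper = up,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e)); NULL
      }
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort(paste0("All optimisation starts failed: ",
                 paste(unique(diagnostics), collapse = "; ")))
  }
  best
}

## Finite-difference Jacobian of the residual vector w.r.t. log-parameters.
fit_jacobian <- function(problem, theta, h = 1e-5) {
  lt <- log(theta)
  r0 <- as.numeric(residual_vector(problem, theta))
  J <- matrix(NA_real_, nrow = length(r0), ncol = length(lt))
  for (j in seq_along(lt)) {
    up <- lt; up[j] <- up[j] + h
    dn <- lt; dn[j] <- dn[j] - h
    ru <- as.numeric(residual_vector(problem, setNames(exp(up), names(theta))))
    rd <- as.numeric(residual_vector(problem, setNames(exp(dn), names(theta))))
    J[, j] <- (ru - rd) / (2 * h)
  }
  J
}

finish_fit <- function(problem, opt, n_starts, seed) {
  theta <- setNames(exp(opt$par), problem$par_names)
  p <- length(theta)

  # fitted values + linear-scale RMSE
  fitted <- purrr::map_dfr(seq_along(problem$cycles), function(i) {
    cy <- problem$cycles[[i]]
    par <- theta_to_params(problem, theta, i)
    obs <- cy$observations
    sim_t <- sort(unique(c(0, obs$time)))
    traj <- simulate_wbc(problem$spec, par, problem$consts, problem$pk,
                         cy$schedule, horizon = cycle_horizon(cy),
                         times = sim_t)
    tibble(cycle = cy$id, time = obs$time, observed = obs$wbc,
           predicted = traj$wbc[match(obs$time, traj$time)])
  })
  n_obs <- nrow(fitted)

  # Gauss-Newton covariance sigma^2 (J'J)^-1, parameters on the log scale,
  # then transformed to the natural scale.
  J <- fit_jacobian(problem, theta)
  r0 <- as.numeric(residual_vector(problem, theta))
  dof <- max(length(r0) - p, 1)
  sigma2 <- sum(r0^2) / dof
  jtj <- crossprod(J)
  cov_log <- tryCatch(sigma2 * solve(jtj), error = function(e) NULL)
  singular <- is.null(cov_log)
  if (singular) {
    cov_nat <- matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
    rse <- setNames(rep(NA_real_, p), names(theta))
    warn("Singular information matrix: covariance and RSEs are undefined.")
  } else {
    cov_log <- (cov_log + t(cov_log)) / 2
    D <- diag(theta, p)
    cov_nat <- D %*% cov_log %*% D
    dimnames(cov_nat) <- list(names(theta), names(theta))
    rse <- setNames(100 * sqrt(pmax(diag(cov_log), 0)), names(theta))
    cors <- stats::cov2cor(cov_nat)
    hi <- which(abs(cors) > 0.9 & row(cors) < col(cors), arr.ind = TRUE)
    if (nrow(hi)) {
      pairs <- apply(hi, 1, function(ix) {
        paste(names(theta)[ix[1]], names(theta)[ix[2]], sep = "~")
      })
      warn(paste0("High parameter correlation (>0.9): ",
                  paste(pairs, collapse = ", ")))
    }
  }
  structure(
    list(problem = problem, estimates = theta,
         params = lapply(seq_along(problem$cycles), function(i)
           theta_to_params(problem, theta, i)),
         objective = opt$deviance, covariance = cov_nat, rse = rse,
         singular = singular,
         residuals = r0, fitted = fitted, n_obs = n_obs,
         rmse = sqrt(mean((fitted$predicted - fitted$observed)^2)),
         n_starts = n_starts, seed = seed, niter = opt$niter),
    class = "myelo_fit"
  )
}

#' Personalise a WBC model to one consolidation cycle
#'
#' Estimates the model parameters (`B`, `slope`, `k_tr`, `gamma`, plus
#' initial-state parameters per the model's initial-condition strategy) by
#' multistart Levenberg-Marquardt nonlinear least squares on log-scale
#' residuals, with the I3 steady-state deviation penalty weighted by `alpha`.
#' The reported RMSE is computed on the linear G/L scale.
#'
#' @param cycle A [cycle_data()] object.
#' @param spec A [model_spec()].
#' @param consts A [model_constants()]; defaults to the reference constants.
#' @param pk A [pk_params()]; defaults to [pk_params_arac()].
#' @param alpha Steady-state penalty weight for I3 (default 1/2500).
#' @param scale Fitting scale for the data residuals, `"log"` (default) or
#'   `"linear"`.
#' @param n_starts Number of multistart points (first is data-informed).
#' @param seed Seed for the multistart sampling.
#' @param bounds Optional bounds list as in [default_fit_bounds()].
#' @return An object of class `myelo_fit` with elements `estimates` (named
#'   vector), `params` (per-cycle [pd_params()]), `objective`, `covariance`
#'   (natural scale), `rse` (%), `fitted` (tibble with observed/predicted),
#'   and `rmse` (G/L). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' spec <- model_spec("M5")
#' cohort <- simulate_cohort(cohort_spec(n_patients = 1, seed = 7), spec)
#' fit <- fit_cycle(cohort[[1]], spec, n_starts = 2)
#' glance(fit)
#' }
#' @export
fit_cycle <- function(cycle, spec, consts = model_constants(),
                      pk = pk_params_arac(), alpha = 1 / 2500,
                      scale = c("log", "linear"), n_starts = 20, seed = 1,
                      bounds = NULL) {
  stopifnot(inherits(cycle, "cycle_data"))
  problem <- fit_problem(cycle, spec, consts, pk, alpha, scale, bounds)
  opt <- fit_optimise(problem, n_starts = n_starts, seed = seed)
  finish_fit(problem, opt, n_starts, seed)
}

#' Personalise a WBC model to all cycles of a patient
#'
#' Jointly fits one set of core parameters (`B`, `slope`, `k_tr`, `gamma`)
#' to all of a patient's cycles. Initial-state parameters (`B0`, `xpr0`,
#' `xtr0`) are per-cycle; each cycle restarts with a drug-free PK state
#' (prior Ara-C has no PK carry-over across cycles).
#'
#' @param cycles List of [cycle_data()] objects for one patient.
#' @inheritParams fit_cycle
#' @return A `myelo_fit`, as for [fit_cycle()].
#' @export
fit_patient <- function(cycles, spec, consts = model_constants(),
                        pk = pk_params_arac(), alpha = 1 / 2500,
                        scale = c("log", "linear"), n_starts = 20, seed = 1,
                        bounds = NULL) {
  if (inherits(cycles, "cycle_data")) cycles <- list(cycles)
  problem <- fit_problem(cycles, spec, consts, pk, alpha, scale, bounds)
  opt <- fit_optimise(problem, n_starts = n_starts, seed = seed)
  finish_fit(problem, opt, n_starts, seed)
}

#' @export
print.myelo_fit <- function(x, ...) {
  cat(sprintf("<myelo_fit> %s, %d cycle(s), %d observations\n",
              x$problem$spec$id, length(x$problem$cycles), x$n_obs))
  cat(sprintf("  objective %.4g, RMSE %.3f G/L\n", x$objective, x$rmse))
  est <- x$estimates
  cat("  ", paste(sprintf("%s = %.3g", names(est), est), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Pooled root-mean-squared error
#'
#' RMSE between predicted and observed WBC counts on the linear G/L scale,
#' pooled over all supplied pairs. Accepts either two numeric vectors or a
#' list of `myelo_fit`/prediction objects whose `fitted` tibbles are stacked.
#'
#' @param predicted Numeric vector of predictions, or a list of fits.
#' @param observed Numeric vector of observations (ignored when `predicted`
#'   is a list of fits).
#' @return A single RMSE value (G/L).
#' @examples
#' pooled_rmse(c(2, 3), c(1, 3)) # sqrt(0.5)
#' @export
pooled_rmse <- function(predicted, observed = NULL) {
  if (is.list(predicted) && !is.data.frame(predicted)) {
    tabs <- lapply(predicted, function(f) {
      if (inherits(f, "myelo_fit")) f$fitted
      else if (is.data.frame(f)) f
      else abort("Unsupported element in `predicted`.")
    })
    tab <- dplyr::bind_rows(tabs)
    predicted <- tab$predicted; observed <- tab$observed
  } else if (inherits(predicted, "myelo_fit")) {
    observed <- predicted$fitted$observed
    predicted <- predicted$fitted$predicted
  }
  if (!length(predicted) || length(predicted) != length(observed)) {
    abort("Need matched non-empty predicted/observed values.")
  }
  sqrt(mean((predicted - observed)^2))
}
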