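#' Fit the two-compartment PK model to pooled concentration data
#'
#' Estimates `k10`, `k12`, `k21` and `Vc` from concentration-time records by
#' naive pooling: all records are treated as one subject and the sum of
#' squared log residuals `log(observed) - log(x1(t)/Vc)` is minimised by
#' multistart Levenberg-Marquardt (the exponential error model
#' `eta = (x1/Vc) e^eps` becomes additive on the log scale). The PK state
#' starts drug-free, `x1(0) = x2(0) = 0`.
#'
#' @param data Data frame with columns `time` (days) and `conc` (mg/L); all
#'   concentrations must be positive.
#' @param schedule The [infusion_schedule()] under which the concentrations
#'   were sampled.
#' @param start A [pk_params()] starting point (default: reference Ara-C
#'   estimates).
#' @param n_starts Number of multistart points (>= 10 recommended); starts
#'   after the first are log-uniform over `span^-1` to `span` times `start`.
#' @param span Multistart box half-width as a multiplicative factor.
#' @param seed Seed for multistart sampling.
#' @return An object of class `pk_fit`: `params` (the fitted [pk_params()]),
#'   `estimates` (named vector, rates in 1/h, `vc` in L, plus derived `cl`,
#'   `q`, `vp`), `rse` (%), `covariance` (log-scale), `objective`, `fitted`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' sched <- kern_sampling_schedule()
#' dat <- gen_pk_concentration_data(pk_params_arac(), sched,
#'                                  kern_sampling_times(), sigma_log = 0)
#' fit <- fit_pk(dat, sched, n_starts = 3)
#' tidy(fit)
#' @export
fit_pk <- function(data, schedule, start = pk_params_arac(), n_starts = 10,
                   span = 100, seed = 1) {
  data <- as_tibble(data)
  if (!all(c("time", "conc") %in% names(data))) {
    abort("`data` must have columns `time` and `conc`.")
  }
  if (any(data$conc <= 0)) abort("Concentrations must be > 0 (log residuals).")
  horizon <- max(data$time) + 1
  start_h <- c(k10 = start$k10, k12 = start$k12, k21 = start$k21,
               vc = start$vc) / c(24, 24, 24, 1)

  resid_fn <- function(lt) {
    th <- exp(lt)
    p <- pk_params(th[1], th[2], th[3], th[4], per = "hour")
    x1 <- pk_solution(p, schedule, horizon)(data$time)[, "x1"]
    log(pmax(x1 / p$vc, 1e-12)) - log(data$conc)
  }

  lo <- log(start_h / span); up <- log(start_h * span)
  starts <- list(log(start_h))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (k in seq_len(max(n_starts - 1, 0))) {
    starts[[k + 1]] <- runif(4, lo, up)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lo, upper = up,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("All PK multistart fits failed.")

  th <- setNames(exp(best$par), c("k10", "k12", "k21", "vc"))
  params <- pk_params(th[1], th[2], th[3], th[4], per = "hour")
  macro <- micro_to_macro(params)

  # finite-difference Jacobian on the log scale
  h <- 1e-6
  r0 <- resid_fn(best$par)
  J <- vapply(seq_along(best$par), function(j) {
    up_ <- best$par; up_[j] <- up_[j] + h
    dn_ <- best$par; dn_[j] <- dn_[j] - h
    (resid_fn(up_) - resid_fn(dn_)) / (2 * h)
  }, numeric(length(r0)))
  dof <- max(length(r0) - 4, 1)
  sigma2 <- sum(r0^2) / dof
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  singular <- is.null(cov_log)
  if (singular) {
    warn("Singular information matrix; PK RSEs undefined.")
    rse <- setNames(rep(NA_real_, 7),
                    c("k10", "k12", "k21", "vc", "cl", "q", "vp"))
    cov_log <- matrix(NA_real_, 4, 4)
  } else {
    cov_log <- (cov_log + t(cov_log)) / 2
    # delta method on the log scale for derived macro constants:
    # log cl = log k10 + log vc, log q = log k12 + log vc,
    # log vp = log k12 + log vc - log k21
    L <- rbind(diag(4),
               cl = c(1, 0, 0, 1), q = c(0, 1, 0, 1), vp = c(0, 1, -1, 1))
    v <- diag(L %*% cov_log %*% t(L))
    rse <- setNames(100 * sqrt(pmax(v, 0)),
                    c("k10", "k12", "k21", "vc", "cl", "q", "vp"))
  }
  dimnames(cov_log) <- list(c("k10", "k12", "k21", "vc"),
                            c("k10", "k12", "k21", "vc"))
  est <- c(th, cl = unname(macro["cl"]), q = unname(macro["q"]),
           vp = unname(macro["vp"]))
  fitted <- tibble(time = data$time, observed = data$conc,
                   predicted = exp(r0 + log(data$conc)))
  structure(list(params = params, estimates = est, rse = rse,
                 covariance = cov_log, singular = singular,
                 objective = best$deviance, residuals = r0,
                 fitted = fitted, n_obs = nrow(data)),
            class = "pk_fit")
}

#' Relative standard errors of a fit
#'
#' `RSE_i = 100 * sqrt(cov_ii) / estimate_i`; for fits parameterised on the
#' log scale this equals `100 * sqrt(diag(cov_log))`.
#'
#' @param fit A `pk_fit` or `myelo_fit`.
#' @return Named vector of RSEs in percent (`NA` where undefined).
#' @export
pk_rse <- function(fit) {
  stopifnot(inherits(fit, "pk_fit") || inherits(fit, "myelo_fit"))
  fit$rse
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %d pooled concentrations, objective %.4g\n",
              x$n_obs, x$objective))
  e <- x$estimates
  cat(sprintf("  CL %.4g L/h  Q %.4g L/h  Vc %.4g L  Vp %.4g L\n",
              e["cl"], e["q"], e["vc"], e["vp"]))
  cat(sprintf("  k10 %.4g  k12 %.4g  k21 %.4g 1/h\n",
              e["k10"], e["k12"], e["k21"]))
  invisible(x)
}
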