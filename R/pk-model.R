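#' Two-compartment Ara-C pharmacokinetic parameters
#'
#' Micro-constant parameterisation of the linear two-compartment disposition
#' model for intravenous cytarabine (Ara-C): central amount `x1`, peripheral
#' amount `x2`,
#' \deqn{\dot x_1 = -(k_{10}+k_{12})x_1 + k_{21}x_2 + u(t),\qquad
#'       \dot x_2 = k_{12}x_1 - k_{21}x_2,}
#' with `u(t)` the infusion rate in mg/day. Rate constants are quoted in 1/h
#' (the usual reporting convention) and converted to 1/day internally, since
#' dosing records and WBC observations are on a day scale.
#'
#' @param k10 Elimination rate constant from the central compartment (1/h).
#' @param k12,k21 Distribution rate constants (1/h).
#' @param vc Central volume of distribution (L).
#' @param per Unit of the supplied rate constants, `"hour"` (default, the
#'   reporting convention) or `"day"`.
#' @return An object of class `pk_params`: a list with elements `k10`, `k12`,
#'   `k21` (1/day) and `vc` (L).
#' @examples
#' pk <- pk_params(k10 = 4.0955, k12 = 0.1109, k21 = 0.5366, vc = 37.6571)
#' micro_to_macro(pk)
#' @export
pk_params <- function(k10, k12, k21, vc, per = c("hour", "day")) {
  per <- match.arg(per)
  vals <- c(k10 = k10, k12 = k12, k21 = k21, vc = vc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All PK parameters (k10, k12, k21, vc) must be finite and > 0.")
  }
  f <- if (per == "hour") 24 else 1
  structure(
    list(k10 = unname(k10 * f), k12 = unname(k12 * f),
         k21 = unname(k21 * f), vc = unname(vc)),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params> (rates in 1/day)\n")
  cat(sprintf("  k10 = %.4g  k12 = %.4g  k21 = %.4g  vc = %.4g L\n",
              x$k10, x$k12, x$k21, x$vc))
  m <- micro_to_macro(x)
  cat(sprintf("  CL = %.4g L/h  Q = %.4g L/h  Vp = %.4g L\n",
              m["cl"], m["q"], m["vp"]))
  invisible(x)
}

#' Reference Ara-C PK parameter estimates
#'
#' The pooled-fit estimates for high-dose Ara-C used as fixed constants in all
#' WBC-model computations: CL 154.225 L/h, Q 4.1761 L/h, Vc 37.6571 L,
#' Vp 7.7825 L (equivalently k10 4.0955, k12 0.1109, k21 0.5366 1/h).
#'
#' @return A `pk_params` object.
#' @export
pk_params_arac <- function() {
  macro_to_micro(cl = 154.225, q = 4.1761, vc = 37.6571, vp = 7.7825)
}

#' Convert macro PK constants to micro rate constants (and back)
#'
#' `macro_to_micro()` maps clearance-style constants to the micro-constant
#' parameterisation via `k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`;
#' `micro_to_macro()` is its inverse.
#'
#' @param cl Clearance (L/h).
#' @param q Intercompartmental clearance (L/h).
#' @param vc,vp Central and peripheral volumes (L).
#' @return `macro_to_micro()`: a [pk_params()] object. `micro_to_macro()`: a
#'   named numeric vector with `cl`, `q` (L/h), `vc`, `vp` (L).
#' @examples
#' p <- macro_to_micro(cl = 154.225, q = 4.1761, vc = 37.6571, vp = 7.7825)
#' micro_to_macro(p)
#' @export
macro_to_micro <- function(cl, q, vc, vp) {
  vals <- c(cl = cl, q = q, vc = vc, vp = vp)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All macro PK constants (cl, q, vc, vp) must be finite and > 0.")
  }
  pk_params(k10 = cl / vc, k12 = q / vc, k21 = q / vp, vc = vc, per = "hour")
}

#' @rdname macro_to_micro
#' @param params A [pk_params()] object.
#' @export
micro_to_macro <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  # back to 1/h for the macro constants
  k10 <- params$k10 / 24; k12 <- params$k12 / 24; k21 <- params$k21 / 24
  c(cl = k10 * params$vc, q = k12 * params$vc,
    vc = params$vc, vp = k12 * params$vc / k21)
}

## Eigen-decomposition of the disposition matrix
##   A = [ -(k10+k12)  k21 ; k12  -k21 ]   (1/day)
## Positive rates give two distinct real negative eigenvalues, so the
## piecewise-constant-input solution has an exact closed form.
pk_eigen <- function(params) {
  a <- params$k10 + params$k12
  c_ <- params$k21
  tr <- -(a + c_)
  disc <- (a - c_)^2 + 4 * params$k12 * params$k21
  sq <- sqrt(disc)
  lam <- c((tr + sq) / 2, (tr - sq) / 2)
  m <- (lam + a) / c_                      # eigenvectors (1, m_i)
  vinv_det <- m[2] - m[1]
  list(lam = lam, m = m, vinv_det = vinv_det, a = a)
}

## Propagate (x1, x2) over dt (vector allowed) under constant input rate r
## (mg/day into the central compartment). Returns a 2-column matrix.
pk_propagate <- function(params, eg, x0, r, dt) {
  # steady state under constant input: A xss = -b, b = (r, 0)
  xss <- c(r / params$k10, r * params$k12 / (params$k10 * params$k21))
  d <- x0 - xss
  # w = V^{-1} d with V = [1 1; m1 m2]
  w1 <- (eg$m[2] * d[1] - d[2]) / eg$vinv_det
  w2 <- (-eg$m[1] * d[1] + d[2]) / eg$vinv_det
  e1 <- exp(eg$lam[1] * dt)
  e2 <- exp(eg$lam[2] * dt)
  x1 <- xss[1] + e1 * w1 + e2 * w2
  x2 <- xss[2] + e1 * w1 * eg$m[1] + e2 * w2 * eg$m[2]
  cbind(x1 = x1, x2 = x2)
}

## Piecewise-constant infusion rate profile of a schedule: a data frame of
## segments [from, to) with total rate (mg/day). Overlapping infusions sum.
schedule_segments <- function(schedule, horizon) {
  ev <- as.data.frame(schedule)
  if (nrow(ev) > 0 && any(ev$duration <= 0)) {
    abort("Zero- or negative-duration dose events are not supported.")
  }
  bounds <- sort(unique(c(0, ev$start, ev$start + ev$duration, horizon)))
  bounds <- bounds[bounds <= horizon + 1e-12]
  if (max(bounds) < horizon) bounds <- c(bounds, horizon)
  from <- head(bounds, -1); to <- tail(bounds, -1)
  mid <- (from + to) / 2
  rate <- vapply(mid, function(t) {
    act <- ev$start <= t & t < ev$start + ev$duration
    sum(ev$amount[act] / ev$duration[act])
  }, numeric(1))
  data.frame(from = from, to = to, rate = rate)
}

#' Simulate the two-compartment Ara-C PK model
#'
#' Computes central and peripheral Ara-C amounts under an infusion schedule by
#' exact piecewise propagation of the linear disposition system (eigenvalue
#' closed form between dose-event boundaries). Initial state is drug-free,
#' `x1(0) = x2(0) = 0`.
#'
#' @param params A [pk_params()] object.
#' @param schedule An [infusion_schedule()] (BSA-adjusted amounts in mg).
#' @param times Increasing vector of output times (days).
#' @return A tibble with columns `time` (days), `x1`, `x2` (mg) and `conc`
#'   (central concentration `x1/vc`, mg/L).
#' @examples
#' pk <- pk_params_arac()
#' sched <- build_schedule("D135", bsa = 1.78)
#' simulate_pk(pk, sched, times = seq(0, 10, by = 0.1))
#' @export
simulate_pk <- function(params, schedule, times) {
  stopifnot(inherits(params, "pk_params"))
  if (is.unsorted(times, strictly = FALSE)) {
    abort("`times` must be non-decreasing.")
  }
  if (any(times < 0)) abort("`times` must be non-negative.")
  fn <- pk_solution(params, schedule, horizon = max(times, 1))
  st <- fn(times)
  tibble(time = times, x1 = st[, 1], x2 = st[, 2], conc = st[, 1] / params$vc)
}

## Segment decomposition with the PK state propagated to every segment start.
pk_segments <- function(params, schedule, horizon) {
  eg <- pk_eigen(params)
  seg <- schedule_segments(schedule, horizon)
  n <- nrow(seg)
  states <- matrix(0, nrow = n + 1, ncol = 2) # state at each segment start
  for (i in seq_len(n)) {
    states[i + 1, ] <- pk_propagate(params, eg, states[i, ], seg$rate[i],
                                    seg$to[i] - seg$from[i])
  }
  list(eg = eg, seg = seg, states = states)
}

## Closed-form coefficients of x1(t) on segment i:
## x1(t) = xss1 + w1 exp(lam1 (t - from)) + w2 exp(lam2 (t - from)).
pk_segment_coefs <- function(params, pkseg, i) {
  eg <- pkseg$eg
  r <- pkseg$seg$rate[i]
  xss <- c(r / params$k10, r * params$k12 / (params$k10 * params$k21))
  d <- pkseg$states[i, ] - xss
  w1 <- (eg$m[2] * d[1] - d[2]) / eg$vinv_det
  w2 <- (-eg$m[1] * d[1] + d[2]) / eg$vinv_det
  list(from = pkseg$seg$from[i], xss1 = xss[1], w1 = w1, w2 = w2,
       lam1 = eg$lam[1], lam2 = eg$lam[2])
}

## Exact PK solution as a vectorised function of time, used both for PK
## output grids and as the drug forcing inside the WBC ODEs.
pk_solution <- function(params, schedule, horizon) {
  pkseg <- pk_segments(params, schedule, horizon)
  eg <- pkseg$eg; seg <- pkseg$seg; states <- pkseg$states
  function(t) {
    t <- pmin(pmax(t, 0), horizon)
    idx <- findInterval(t, seg$from, rightmost.closed = TRUE)
    idx[idx < 1] <- 1
    out <- matrix(0, nrow = length(t), ncol = 2)
    for (i in unique(idx)) {
      sel <- idx == i
      out[sel, ] <- pk_propagate(params, eg, states[i, ], seg$rate[i],
                                 t[sel] - seg$from[i])
    }
    colnames(out) <- c("x1", "x2")
    out
  }
}

#' Washout time of the PK system
#'
#' First time after the start of dosing at which both compartment amounts have
#' fallen below `threshold` (default 1e-6 mg), located by a fine grid search
#' refined with root bracketing on the exact solution.
#'
#' @inheritParams simulate_pk
#' @param threshold Amount threshold in mg.
#' @param horizon Search horizon in days.
#' @return Washout time in days (`NA` if not reached within `horizon`).
#' @export
pk_washout_time <- function(params, schedule, threshold = 1e-6,
                            horizon = 30) {
  fn <- pk_solution(params, schedule, horizon)
  ev <- as.data.frame(schedule)
  t_end <- if (nrow(ev)) max(ev$start + ev$duration) else 0
  grid <- seq(t_end, horizon, by = 1e-3)
  mx <- apply(fn(grid), 1, max)
  below <- which(mx < threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(grid[1])
  f <- function(t) max(fn(t)) - threshold
  uniroot(f, c(grid[i - 1], grid[i]), tol = 1e-10)$root
}
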