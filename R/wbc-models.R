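#' Structural WBC model variants M1-M12
#'
#' The twelve model variants share the maturation-chain skeleton
#' \deqn{\dot x_{pr} = (F - G)\,x_{pr},\quad
#'       \dot x_{tr,1} = G(x_{pr} - x_{tr,1}),\ \dots,\quad
#'       \dot x_{ma} = G\,x_{tr,n} - k_{ma} x_{ma},}
#' and differ in the number of transit compartments `n_tr`, the
#' initial-condition strategy (`I1` full steady state, `I2` estimated initial
#' circulating count `B0`, `I3` all initial states estimated under a
#' steady-state penalty), and the proliferation/maturation laws `F` and `G`:
#'
#' * M1/M2/M3: `(1-E) k_tr (B/x_ma)^gamma`, `G = k_tr`, with `n_tr` = 6/3/1, I1.
#' * M4: as M3 with I2; M5: as M3 with I3 (the reference model).
#' * M6: direct kill, net rate `k_tr (B/x_ma)^gamma - E` on `x_pr`.
#' * M7: `k_tr` replaced by `k_tr/S(x1)` throughout (also in `G`).
#' * M8: `F` scaled by `1/S(x1)`.
#' * M9: `F` scaled by `1/S(x1)` and exponent `gamma S(x1)`.
#' * M10: exponent `gamma S(x1)` only.
#' * M11: feedback from bone-marrow cells, `(B_bm/(0.01 x_pr + 0.99 x_tr))^gamma`.
#' * M12: M11's feedback with M10's `gamma S(x1)` exponent.
#'
#' Here `E = slope * log(1 + c_V x1)` is the log-linear drug effect and
#' `S(x1) = 1 + log(1 + c_V x1)` the secondary-effect scaling.
#'
#' @param id Model id, `"M1"` ... `"M12"`.
#' @param init Optional override of the initial-condition strategy
#'   (`"I1"`, `"I2"`, `"I3"`), e.g. `model_spec("M10", init = "I1")` for
#'   population-style simulation studies.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("M10")
#' @export
model_spec <- function(id, init = NULL) {
  ids <- paste0("M", 1:12)
  if (!id %in% ids) abort(sprintf("Unknown model id '%s'.", id))
  n_tr <- switch(id, M1 = 6, M2 = 3, 1)
  default_init <- switch(id, M1 = , M2 = , M3 = "I1", M4 = "I2", "I3")
  init <- init %||% default_init
  if (!init %in% c("I1", "I2", "I3")) abort("`init` must be I1, I2 or I3.")
  structure(
    list(
      id = id, n_tr = n_tr, init = init,
      direct_kill = id == "M6",
      g_scaled_by_s = id == "M7",
      f_scaled_by_s = id %in% c("M7", "M8", "M9"),
      gamma_scaled_by_s = id %in% c("M9", "M10", "M12"),
      bone_marrow_feedback = id %in% c("M11", "M12")
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: n_tr = %d, init = %s\n", x$id, x$n_tr, x$init))
  invisible(x)
}

#' Fixed model constants
#'
#' Constants shared by all WBC model variants: the death rate of circulating
#' WBC `k_ma`, the cytarabine molar mass, and the unit-consistency constant
#' `c_V = 1000/(Vc * MM_cyt)` converting a central amount in mg to a central
#' concentration in umol/L, the scale on which the drug effect `E` and the
#' secondary effect `S` operate.
#'
#' @param vc Central PK volume (L), used to form `c_V`.
#' @param k_ma Death rate of circulating WBC (1/day). The default corresponds
#'   to a 7-hour circulating half-life, `24 log(2)/7`.
#' @param mm_cyt Molar mass of cytarabine (g/mol).
#' @return An object of class `model_constants` with fields `k_ma`, `mm_cyt`,
#'   `vc` and `c_v` (per mg).
#' @export
model_constants <- function(vc = pk_params_arac()$vc,
                            k_ma = 24 * log(2) / 7,
                            mm_cyt = 243.22) {
  if (any(c(vc, k_ma, mm_cyt) <= 0)) abort("Model constants must be > 0.")
  structure(list(k_ma = k_ma, mm_cyt = mm_cyt, vc = vc,
                 c_v = 1000 / (vc * mm_cyt)),
            class = "model_constants")
}

#' Personalised PD parameters
#'
#' The four personalised parameters of every model variant -- baseline WBC
#' `B` (G/L), drug-effect `slope` (per log-concentration), transition rate
#' `k_tr` (1/day) and feedback exponent `gamma` -- plus, depending on the
#' initial-condition strategy, the initial circulating count `B0` (I2/I3) and
#' the initial proliferating/transit values `xpr0`, `xtr0` (I3). The derived
#' bone-marrow baseline is `B_bm = B * k_ma / k_tr`.
#'
#' @param B Baseline circulating WBC count (G/L).
#' @param slope Drug-effect slope (dimensionless, per log(1 + c_V x1)).
#' @param k_tr Transition/proliferation rate (1/day).
#' @param gamma Feedback exponent (dimensionless).
#' @param B0 Initial circulating WBC count (G/L); required for I2/I3.
#' @param xpr0,xtr0 Initial proliferating and transit-compartment values
#'   (G/L-equivalent); required for I3.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(B, slope, k_tr, gamma, B0 = NULL, xpr0 = NULL,
                      xtr0 = NULL) {
  core <- c(B = B, slope = slope, k_tr = k_tr, gamma = gamma)
  if (any(!is.finite(core)) || any(core <= 0)) {
    abort("B, slope, k_tr and gamma must all be finite and > 0.")
  }
  for (v in list(B0 = B0, xpr0 = xpr0, xtr0 = xtr0)) {
    if (!is.null(v) && (!is.finite(v) || v <= 0)) {
      abort("Initial-state parameters must be > 0 when supplied.")
    }
  }
  structure(list(B = B, slope = slope, k_tr = k_tr, gamma = gamma,
                 B0 = B0, xpr0 = xpr0, xtr0 = xtr0),
            class = "pd_params")
}

b_bm <- function(params, consts) params$B * consts$k_ma / params$k_tr

#' Drug effect and secondary-effect scaling
#'
#' `pd_effect()` is the log-linear pharmacodynamic effect
#' `E = slope * log(1 + c_V x1)`; `saturation()` is the secondary-effect
#' scaling `S(x1) = 1 + log(1 + c_V x1)` applied to rates and exponents in
#' models M7-M12. Both are monotone increasing in the central Ara-C amount
#' `x1`, with `E(0) = 0` and `S(0) = 1`.
#'
#' @param x1 Central-compartment Ara-C amount (mg), non-negative.
#' @param slope Drug-effect slope.
#' @param c_v Unit-consistency constant (per mg), see [model_constants()].
#' @return Numeric vector of effects.
#' @examples
#' cst <- model_constants()
#' pd_effect(c(0, 100, 400), slope = 5, c_v = cst$c_v)
#' saturation(c(0, 100, 400), c_v = cst$c_v)
#' @export
pd_effect <- function(x1, slope, c_v) {
  if (any(x1 < 0)) abort("`x1` must be non-negative.")
  slope * log1p(c_v * x1)
}

#' @rdname pd_effect
#' @export
saturation <- function(x1, c_v) {
  if (any(x1 < 0)) abort("`x1` must be non-negative.")
  1 + log1p(c_v * x1)
}

## Feedback denominators are floored to avoid blow-up in transient deep
## suppression; the floor is far below any physical WBC count.
.state_floor <- 1e-12

#' Proliferation and maturation rates of a model variant
#'
#' Evaluates the proliferation law `F` (per day; for M6 the net per-cell rate
#' including the direct-kill term) and the maturation law `G` at a given
#' state, exactly as tabulated for M1-M12.
#'
#' @param spec A [model_spec()].
#' @param params A [pd_params()].
#' @param consts A [model_constants()].
#' @param x1 Central Ara-C amount (mg).
#' @param xma Circulating WBC count (G/L).
#' @param xpr,xtr Proliferating and (summed) transit-compartment values,
#'   needed for the bone-marrow feedback variants M11/M12.
#' @return Rate in 1/day.
#' @export
proliferation_rate <- function(spec, params, consts, x1, xma,
                               xpr = NULL, xtr = NULL) {
  E <- pd_effect(x1, params$slope, consts$c_v)
  S <- saturation(x1, consts$c_v)
  gam <- if (spec$gamma_scaled_by_s) params$gamma * S else params$gamma
  if (spec$bone_marrow_feedback) {
    if (is.null(xpr) || is.null(xtr)) {
      abort("Bone-marrow feedback models need `xpr` and `xtr`.")
    }
    denom <- pmax(0.01 * xpr + 0.99 * xtr, .state_floor)
    fb <- (b_bm(params, consts) / denom)^gam
  } else {
    fb <- (params$B / pmax(xma, .state_floor))^gam
  }
  if (spec$direct_kill) {
    params$k_tr * fb - E
  } else {
    rate <- (1 - E) * params$k_tr * fb
    if (spec$f_scaled_by_s) rate / S else rate
  }
}

#' @rdname proliferation_rate
#' @export
maturation_rate <- function(spec, params, consts, x1) {
  S <- saturation(x1, consts$c_v)
  if (spec$g_scaled_by_s) params$k_tr / S else params$k_tr
}

#' Initial state of the WBC compartments
#'
#' Builds the initial `(x_pr, x_tr, x_ma)` state for the model's
#' initial-condition strategy: I1 the full steady state
#' `(B_bm, ..., B_bm, B)`; I2 steady bone-marrow states with estimated
#' circulating count `B0`; I3 all initial states `(xpr0, xtr0, B0)` estimated.
#'
#' @inheritParams proliferation_rate
#' @return Named numeric vector `xpr`, `xtr1` ... `xtr<n>`, `xma`.
#' @export
initial_state <- function(spec, params, consts) {
  bbm <- b_bm(params, consts)
  n <- spec$n_tr
  if (spec$init == "I1") {
    st <- c(bbm, rep(bbm, n), params$B)
  } else if (spec$init == "I2") {
    if (is.null(params$B0)) abort("I2 requires `B0` in the parameters.")
    st <- c(bbm, rep(bbm, n), params$B0)
  } else {
    if (is.null(params$B0) || is.null(params$xpr0) || is.null(params$xtr0)) {
      abort("I3 requires `B0`, `xpr0` and `xtr0` in the parameters.")
    }
    st <- c(params$xpr0, rep(params$xtr0, n), params$B0)
  }
  names(st) <- c("xpr", paste0("xtr", seq_len(n)), "xma")
  st
}

## Build a specialised vector-field evaluator with all model constants and
## variant flags resolved at construction time (the integrator calls it many
## thousand times per fit, so it avoids S3 dispatch and validation).
make_fast_rhs <- function(spec, params, consts) {
  ktr <- params$k_tr; gam <- params$gamma; B <- params$B
  slope <- params$slope
  cv <- consts$c_v; kma <- consts$k_ma
  bbm <- B * kma / ktr
  n <- spec$n_tr
  gs <- spec$gamma_scaled_by_s; fs <- spec$f_scaled_by_s
  gsc <- spec$g_scaled_by_s; dk <- spec$direct_kill
  bm <- spec$bone_marrow_feedback
  function(x1, y) {
    l <- log1p(cv * x1)
    E <- slope * l
    S <- 1 + l
    G <- if (gsc) ktr / S else ktr
    g <- if (gs) gam * S else gam
    xpr <- y[1]; xma <- y[n + 2]
    fb <- if (bm) {
      (bbm / max(0.01 * xpr + 0.99 * sum(y[2:(n + 1)]), .state_floor))^g
    } else {
      (B / max(xma, .state_floor))^g
    }
    Fr <- if (dk) ktr * fb - E else {
      v <- (1 - E) * ktr * fb
      if (fs) v / S else v
    }
    if (n == 1) {
      c((Fr - G) * xpr, G * (xpr - y[2]), G * y[2] - kma * xma)
    } else {
      xtr <- y[2:(n + 1)]
      c((Fr - G) * xpr, G * (c(xpr, xtr[-n]) - xtr),
        G * xtr[n] - kma * xma)
    }
  }
}

## Vector field of the WBC compartments; x1 is supplied by the PK forcing.
wbc_rhs <- function(spec, params, consts, x1, y) {
  n <- spec$n_tr
  xpr <- y[1]; xtr <- y[2:(n + 1)]; xma <- y[n + 2]
  G <- maturation_rate(spec, params, consts, x1)
  Fr <- proliferation_rate(spec, params, consts, x1, xma,
                           xpr = xpr, xtr = sum(xtr))
  dpr <- (Fr - G) * xpr
  dtr <- numeric(n)
  dtr[1] <- G * (xpr - xtr[1])
  if (n > 1) for (i in 2:n) dtr[i] <- G * (xtr[i - 1] - xtr[i])
  dma <- G * xtr[n] - consts$k_ma * xma
  d <- unname(c(dpr, dtr, dma))
  if (any(!is.finite(d))) {
    abort(paste0("Non-finite derivative at state (",
                 paste(signif(y, 4), collapse = ", "), ")."))
  }
  d
}

#' Simulate a WBC model variant under an infusion schedule
#'
#' Integrates the coupled PK/WBC system. The linear PK subsystem is solved
#' exactly (piecewise closed form) and drives the stiff WBC compartments,
#' which are integrated with `deSolve::lsoda`, breaking at every dose-event
#' boundary so infusion on/off discontinuities are handled exactly.
#'
#' @inheritParams proliferation_rate
#' @param pk A [pk_params()] object.
#' @param schedule An [infusion_schedule()].
#' @param horizon Simulation horizon (days).
#' @param times Output grid (days); default `seq(0, horizon, by = 0.05)`.
#' @param init Optional initial state overriding [initial_state()].
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `wbc_trajectory` with columns `time`, `x1`,
#'   `x2`, `xpr`, `xtr1` ..., `xma` and `wbc` (`= xma`, G/L).
#' @examples
#' spec <- model_spec("M5")
#' par <- pd_params(B = 5.5, slope = 5, k_tr = 0.19, gamma = 0.45,
#'                  B0 = 5.5, xpr0 = 60, xtr0 = 60)
#' traj <- simulate_wbc(spec, par, model_constants(), pk_params_arac(),
#'                      build_schedule("D135"), horizon = 30)
#' recovery_stats(traj)
#' @export
simulate_wbc <- function(spec, params, consts, pk, schedule, horizon = 28,
                         times = NULL, init = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "model_spec"), inherits(params, "pd_params"),
            inherits(consts, "model_constants"), inherits(pk, "pk_params"))
  times <- times %||% seq(0, horizon, by = 0.05)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  horizon <- max(horizon, max(times))
  pkseg <- pk_segments(pk, schedule, horizon)
  rhs_fast <- make_fast_rhs(spec, params, consts)
  y0 <- init %||% initial_state(spec, params, consts)

  ystates <- matrix(NA_real_, nrow = length(times), ncol = length(y0),
                    dimnames = list(NULL, names(y0)))
  y <- y0
  for (i in seq_len(nrow(pkseg$seg))) {
    a <- pkseg$seg$from[i]; b <- pkseg$seg$to[i]
    if (b - a < 1e-12) next
    co <- pk_segment_coefs(pk, pkseg, i)
    xss1 <- co$xss1; w1 <- co$w1; w2 <- co$w2
    lam1 <- co$lam1; lam2 <- co$lam2; t_from <- co$from
    deriv <- function(t, y, p) {
      x1 <- xss1 + w1 * exp(lam1 * (t - t_from)) + w2 * exp(lam2 * (t - t_from))
      if (x1 < 0) x1 <- 0
      list(rhs_fast(x1, y))
    }
    sel <- which(times >= a - 1e-12 & times <= b + 1e-12 & is.na(ystates[, 1]))
    seg_t <- sort(unique(c(a, times[sel], b)))
    sol <- deSolve::lsoda(y, seg_t, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0 || anyNA(sol[, -1])) {
      abort(sprintf("WBC integration failed on [%0.3f, %0.3f].", a, b))
    }
    y <- as.numeric(sol[nrow(sol), -1])
    if (length(sel)) {
      ystates[sel, ] <- sol[match(times[sel], seg_t), -1, drop = FALSE]
    }
  }
  if (anyNA(ystates)) abort("Internal grid assembly failure.")
  pkfun <- pk_solution(pk, schedule, horizon)
  if (min(ystates) < -1e-9) {
    abort("Negative compartment values beyond solver tolerance.")
  }
  pkst <- pkfun(times)
  out <- tibble(time = times, x1 = pkst[, "x1"], x2 = pkst[, "x2"])
  for (j in seq_len(ncol(ystates))) out[[colnames(ystates)[j]]] <- ystates[, j]
  out$wbc <- out$xma
  structure(out, class = c("wbc_trajectory", class(out)),
            spec = spec, params = params, consts = consts,
            schedule = schedule)
}

#' Mean maturation time of the transit chain
#'
#' Returns both the corrected mean maturation time `n_tr/k_tr` and the
#' original convention `(n_tr + 1)/k_tr`, in hours.
#'
#' @param spec A [model_spec()] (only `n_tr` is used).
#' @param k_tr Transition rate (1/day).
#' @return Named numeric vector `corrected`, `original` (hours).
#' @examples
#' mean_maturation_time(model_spec("M3"), k_tr = 0.1875)
#' @export
mean_maturation_time <- function(spec, k_tr) {
  if (k_tr <= 0) abort("`k_tr` must be > 0.")
  c(corrected = 24 * spec$n_tr / k_tr,
    original = 24 * (spec$n_tr + 1) / k_tr)
}
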