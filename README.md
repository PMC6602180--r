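# myelokin

Simulation, personalisation and schedule analysis of white blood cell (WBC)
dynamics during cytarabine (Ara-C) consolidation therapy for acute myeloid
leukaemia (AML).

Consolidation chemotherapy with intermediate/high-dose Ara-C (1–3 g/m²,
twice-daily 3-hour infusions on schedules such as D135, d135, D123, D12)
causes profound myelosuppression: WBC counts fall below the leukopenia
threshold of 1 G/L for a week or more, with a high risk of infection.
`myelokin` is for pharmacometricians and modellers who want to personalise
semi-mechanistic myelosuppression models to almost-daily WBC counts from
individual consolidation cycles, predict upcoming cycles with uncertainty,
and compare dosing schedules by their predicted recovery times.

## The models

Ara-C disposition follows a linear two-compartment model with zero-order
infusion input (amounts `x1`, `x2` in mg):

    dx1/dt = -(k10 + k12) x1 + k21 x2 + u(t)
    dx2/dt =  k12 x1 - k21 x2

with reference estimates CL 154.2 L/h, Q 4.18 L/h, Vc 37.66 L, Vp 7.78 L
obtained by naive-pooled log-scale least squares on high-dose
concentration data (`fit_pk()` re-estimates them from any
concentration–time records).

WBC dynamics follow a Friberg-type transit-compartment model: a
proliferating pool `x_pr`, `n_tr` transit (maturation) compartments, and
circulating cells `x_ma` that die at rate `k_ma`:

    dx_pr/dt  = F x_pr - G x_pr
    dx_tr/dt  = G (x_pr - x_tr)            (chain of n_tr compartments)
    dx_ma/dt  = G x_tr - k_ma x_ma

The drug acts through the log-linear effect `E = slope · ln(1 + c_V x1)`,
and a secondary-effect function `S(x1) = 1 + ln(1 + c_V x1)` modifies
rates or the feedback exponent in the extended variants. Twelve variants
M1–M12 (`model_spec("M1")` … `model_spec("M12")`) cover: 6/3/1 transit
compartments (M1/M2/M3), estimated initial conditions (I2 in M4, penalised
I3 in M5–M12), a direct-kill effect (M6), maturation slowing (M7), damped
feedback (M8, M9), concentration-scaled feedback exponent
`(B/x_ma)^(γ·S(x1))` (M9, M10, M12) and bone-marrow-sensed feedback
(M11, M12). M5 is the reference; M10 is the variant whose predictions
separate dense (D123) from standard (D135) schedules.

Personalisation estimates `B` (baseline WBC, G/L), `slope`, `k_tr` (1/day)
and `γ` — plus per-cycle initial states under I2/I3 — by multistart
Levenberg–Marquardt least squares on log-scale residuals, with the I3
steady-state deviation penalty `α Σ (x(t0) − B_bm)²`, `α = 1/2500`.

## Worked example

Generate a synthetic consolidation cycle, personalise M10 to it, and
compare predicted recovery under the D135 and D123 schedules:

```r
library(myelokin)

spec   <- model_spec("M10")
cohort <- simulate_cohort(cohort_spec(n_patients = 1, seed = 42), spec)
cycle  <- cohort[[1]]
cycle
#> <cycle_data> P01_C1 (patient P01): 27 WBC counts over 27.0 d, schedule D135

fit <- fit_cycle(cycle, spec, n_starts = 2)
fit
#> <myelo_fit> M10, 1 cycle(s), 27 observations
#>   objective 0.4981, RMSE 0.569 G/L
#>   B = 7.11, slope = 4.38, k_tr = 0.196, gamma = 0.564, B0 = 8.52, ...

traj <- predict_cycle(fit, horizon = 45, times = seq(0, 45, 0.05),
                      init = "fitted")
recovery_stats(traj)
#>   t_rec t_leu nadir
#> 1  19.0  6.95 0.592

d123 <- predict_cycle(fit, schedule = build_schedule("D123"), horizon = 45,
                      times = seq(0, 45, 0.05))
recovery_stats(d123)
#>   t_rec t_leu nadir
#> 1  14.2  1.21 0.986
```

The fitted cycle reaches its nadir of 0.59 G/L and recovers above 1 G/L
19.0 days after the first dose; the same personalised model predicts a
4.8-day faster recovery under the denser D123 schedule — the
schedule-separation signature of the concentration-scaled feedback in M10.
`autoplot(traj)`, `autoplot(fit)` and `autoplot(monte_carlo_band(fit))`
draw the trajectories, fits and uncertainty bands; `tidy(fit)` and
`glance(fit)` give broom-style summaries.

Other entry points: `fit_patient()` (joint fit of all cycles of a
patient), `cross_validate_last_cycle()` (held-out prediction),
`discrimination_study()` (recovery-time comparison of schedules across
personalised models, with the no-leukopenia exclusion rule),
`timing_study()` (nadir versus cycle-start shift), `iiv_study()`
(lognormal PK variability propagation), and `read_nonmem()` /
`write_nonmem()` for the nine-column `ID TIME DV CMT AMT RATE DUR MDV
EVID` dataset dialect.

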