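---
title: "Transit-compartment models of Ara-C myelosuppression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transit-compartment models of Ara-C myelosuppression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model family,
the estimation machinery, the numerical choices, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## The coupled PK/PD system

High-dose cytarabine (Ara-C) is given as repeated short infusions
(typically 3 hours, twice daily) during AML consolidation. Its disposition
is described by a linear two-compartment model in amounts (mg), with
zero-order infusion input `u(t)` (mg/day) into the central compartment:

$$\dot x_1 = -(k_{10}+k_{12})\,x_1 + k_{21}\,x_2 + u(t), \qquad
  \dot x_2 = k_{12}\,x_1 - k_{21}\,x_2 .$$

All internal time is in **days** (the dataset convention: a 3-h infusion
has `DUR = 0.125`); rate constants are quoted in 1/h, the reporting
convention, and converted once at construction (`pk_params(..., per =
"hour")`). The reference estimates (`pk_params_arac()`) are CL 154.225 L/h,
Q 4.1761 L/h, Vc 37.6571 L, Vp 7.7825 L. Because the system is linear with
piecewise-constant input, the package solves it **exactly** by eigenvalue
decomposition between dose-event boundaries; positive rate constants always
give two distinct real negative eigenvalues, so no numerical integration or
degeneracy fallback is needed on the PK side. One consequence worth noting:
after a single high-dose infusion both amounts fall below $10^{-6}$ mg in
under two days (`pk_washout_time()`), which justifies restarting every
cycle with a drug-free PK state.

WBC dynamics follow the transit-compartment (Friberg-type) architecture:
proliferating cells $x_{pr}$, a maturation chain $x_{tr,1..n}$, and
circulating cells $x_{ma}$ dying at rate $k_{ma}$:

$$\dot x_{pr} = (F - G)\,x_{pr},\qquad
  \dot x_{tr,i} = G\,(x_{tr,i-1} - x_{tr,i}),\qquad
  \dot x_{ma} = G\,x_{tr,n} - k_{ma}\,x_{ma}.$$

All compartments are expressed per litre of peripheral blood, so $x_{ma}$
is directly the measured WBC count (G/L); bone-marrow compartments are not
literal marrow cell counts and no blood-to-marrow volume conversion is
attempted.

The drug couples to the WBC model through the central amount $x_1$ via

* the log-linear effect $E = \mathrm{slope}\cdot\ln(1 + c_V x_1)$, and
* the secondary-effect scaling $S(x_1) = 1 + \ln(1 + c_V x_1)$.

The twelve structural variants differ in $n_{tr}$ (6/3/1 for M1/M2/M3; 1
from M4 on), the initial-condition strategy (I1/I2/I3, below), and where
$E$ and $S$ enter $F$ and $G$ — see `?model_spec` for the complete table.
M5 (plain $(1-E)k_{tr}(B/x_{ma})^{\gamma}$, I3) is the reference; M10
scales the feedback exponent to $\gamma S(x_1)$, which is what makes its
predicted recovery times schedule-sensitive; M11/M12 sense the feedback
from the bone-marrow pool $0.01\,x_{pr} + 0.99\,x_{tr}$ instead of the
circulating count. In M6 the effect is a direct per-cell kill term
($F = k_{tr}(B/x_{ma})^{\gamma} - E$, deliberately unclipped so the net
rate may be negative).

### The unit constant `c_V`

The defining relation is $c_V = 1/(V_c\,\mathrm{MM}_{cyt})$ with
$\mathrm{MM}_{cyt} = 243.22$ g/mol. Taken literally with $x_1$ in mg and
$V_c$ in L this yields a concentration in mmol/L, for which $c_V x_1$
never exceeds ~0.05 at 3 g/m² peaks — at that scale $E>1$ (the point where
net proliferation turns negative, reached when
$c_V x_1 > e^{1/\mathrm{slope}}-1$) would require slopes of order 20 and
$S$ would never leave 1, erasing every secondary-effect variant. The
package therefore fixes the PD concentration scale as **micromolar**:
$c_V = 1000/(V_c\,\mathrm{MM}_{cyt})$ per mg, giving $c_V x_1 \approx 47$
at peak, $E = 1$ at slopes near 0.3–6, and $S$ up to ~4.9 — consistent
with the slope box $[10^{-3}, 10]$ and with secondary effects that are
actually visible in recovery times. `c_v` is recomputed whenever `Vc`
changes (`model_constants(vc = ...)`), e.g. per draw in `iiv_study()`.

### `k_ma`

The death rate of circulating WBC is fixed, not estimated. The default,
$k_{ma} = 24\ln 2/7 \approx 2.38$/day, corresponds to the conventional
7-hour circulating half-life used by the Quartino/Friberg model line. It
is a configurable argument of `model_constants()`, never hard-coded in
formulas.

## Initial conditions

* **I1** — full steady state: $x_{pr} = x_{tr,i} = B_{bm}$,
  $x_{ma} = B$, with $B_{bm} = B\,k_{ma}/k_{tr}$. Identifiable, but real
  cycles often start off equilibrium.
* **I2** — marrow at steady state, circulating count estimated:
  $x_{ma}(t_0) = B_0$. At $t_0$ (drug-free) the circulating derivative is
  $k_{ma}(B - B_0)$, so rising and falling starts can both be captured.
* **I3** — all initial states estimated, with the penalty
  $\alpha(x_{pr}(t_0)-B_{bm})^2 + \alpha\sum_i (x_{tr,i}(t_0)-B_{bm})^2$,
  $\alpha = 1/2500$, added to the least-squares objective to restore
  identifiability. $B_0$ is deliberately **not** penalised. As
  $\alpha \to \infty$ the initial marrow states are pinned to $B_{bm}$
  and the fit approaches the I1-style fit of the same data (a property
  the test suite asserts).

## Personalisation

`fit_cycle()`/`fit_patient()` estimate $(B, \mathrm{slope}, k_{tr},
\gamma)$ — plus per-cycle $B_0$ (I2/I3) and $x_{pr}(t_0), x_{tr}(t_0)$
(I3) — by Levenberg–Marquardt on **log-parameters** (which enforces
positivity and makes relative standard errors read directly off the
log-scale covariance).

* **Fitting scale.** Data residuals are $\log(\mathrm{pred}) -
  \log(\mathrm{obs})$ by default, matching the multiplicative error
  structure of count data and weighting the nadir region — where counts
  are far below 1 G/L — on equal footing with recovery. A linear scale is
  available (`scale = "linear"`). RMSE values are always reported on the
  linear G/L scale from back-transformed predictions, so they are
  comparable across fitting scales.
* **Bounds.** $B \in [1, 20]$ G/L, slope $\in [10^{-3}, 10]$,
  $k_{tr} \in [0.01, 5]$/day, $\gamma \in [0.01, 10]$; initial states in
  $[10^{-3}, 10\,B_{bm}]$ with $B_{bm}$ evaluated at the data-informed
  start. These bracket published Friberg-type estimates with wide margin.
* **Multistart.** The first start is data-informed ($B$ from the upper
  quartile of the observed counts, $B_0$ from the first observation,
  marrow states at the implied $B_{bm}$); further starts are log-uniform
  perturbations within a decade, drawn under a fixed seed. The default is
  20 starts; in practice the data-informed start reaches the optimum on
  clean synthetic cycles, and the study-scale runs in the test suite use
  1–2 starts to keep total runtime reasonable (40-cycle recovery study:
  ~2 minutes). The returned objective is never worse than any start.
* **Covariance.** Gauss–Newton asymptotics: $\hat\sigma^2 (J^\top
  J)^{-1}$ with $\hat\sigma^2 = \mathrm{RSS}/(n-p)$ and $J$ the
  finite-difference Jacobian at the optimum (central differences, step
  $10^{-5}$ on the log scale). RSE$_i$ = $100\sqrt{(\mathrm{cov}_{\log})_{ii}}$.
  Estimates are reported even when parameter correlations exceed 0.9
  (as happens between $\gamma$ and $k_{tr}$ or slope on single cycles); a
  warning is logged. A singular information matrix flags the fit and
  leaves RSEs undefined rather than failing.
* **Patientwise fits** share the four core parameters across a patient's
  cycles; initial-state parameters stay per-cycle, and each cycle restarts
  with a drug-free PK state (prior Ara-C has no PK carry-over).

The PK parameters are estimated separately (`fit_pk()`) by naive pooling —
all concentration records treated as one subject — with the exponential
error model made additive on the log scale, multistart (≥10 starts over a
$100^{\mp1}$ box) because concentration data digitised from published
figures cannot be assigned to individuals. The PK model is then fixed for
all WBC work; the estimation is over the four parameters with the initial
PK state fixed at zero.

## Prediction and uncertainty

`cross_validate_last_cycle()` fits all but the last cycle and simulates
the held-out cycle under its actual schedule; the held-out observations
never reach the optimiser. The predicted cycle starts from the fitted
steady state $(B_{bm}, B)$ — the natural choice for a cycle whose initial
conditions were never observed; this is a package decision, since the
initialisation of predicted cycles is otherwise underdetermined.

`monte_carlo_band()` draws parameter vectors from the multivariate normal
at (estimate, covariance), resamples draws that leave the positivity/box
bounds (up to 100 attempts per draw; clipping would distort the quantiles)
and reports pointwise 2.5/50/97.5% quantiles of the simulated WBC. A
covariance that fails positive semidefiniteness by rounding is repaired by
eigenvalue clipping, with a warning. Bands from fits on more cycles are
pointwise tighter on average — asserted in the test suite.

## Recovery statistics and schedule analysis

The discrimination currency is the triple (`recovery_stats()`):

* `nadir` — minimum WBC;
* `t_leu` — total time with WBC ≤ 1 G/L;
* `t_rec` — first up-crossing of 1 G/L after the nadir, measured from
  cycle start, `NA` if the trajectory never drops below threshold.

Simulated values are read off a dense grid (0.05 day) with linear
interpolation of the crossing; `observed_recovery_stats()` evaluates the
same definitions on the discrete measurement grid (first measurement above
threshold after the minimum; `t_leu` counts measurement days at or below
threshold), which makes observed `t_rec` systematically a little larger
than the dense simulated value — by construction at most one sampling
interval on an almost-daily grid. Clinical `t_rec` is referenced to the
first dose (time 0 of the cycle), and `t_leu` counts measurement days, not
calendar days — both choices the data dialect leaves open.

`discrimination_study()` simulates every personalised model (PM) under
each candidate schedule from its fitted steady state and summarises
median/SD/min/max per model × schedule, plus the within-PM median
difference of `t_rec` between schedules. A personalised cycle is excluded
entirely if **any** of its predictions (any model, any schedule) produces
no WBC count below threshold — medians of recovery times must not be
taken over absent leukopenia episodes. Inclusion plus exclusion always
partitions the input.

`timing_study()` translates the dosing block of a personalised cycle day
by day (±10 days). Because a 10-day-earlier start would precede the
simulation origin, the block sits behind a 10-day drug-free pad inside the
horizon; the WBC state starts at the fitted initial conditions and evolves
freely until dosing begins. For a patient whose cycle starts in
post-overshoot (circulating count and marrow above steady state — the
situation after a preceding cycle's rebound), earlier starts hit higher
counts and give higher nadirs; the test suite asserts monotone
non-increase of the nadir across the ±10-day range with a numerical slack
of 0.005 G/L, i.e. at figure resolution, since damped feedback
oscillations produce sub-0.005 wiggles once the transient has decayed.

`iiv_study()` propagates lognormal inter-individual variability on CL
(CV 45%) and Vc (CV 70%) with `Q`, `Vp` fixed, re-deriving the micro
constants and `c_V` per draw; the lognormal is parameterised to preserve
the median (`sdlog = sqrt(log(1+CV^2))`). Population PD parameters default
to the generator's nominal patient (below). The concentration-scaled
feedback model (M10, used with I1 for this population-style study) keeps a
visibly larger D135−D123 recovery-time separation than M3 even under this
much PK noise.

## The synthetic cohort generator

`simulate_cohort()` stands in for the clinical consolidation datasets,
emulating their statistical structure: 23 patients with 1/2/3 consecutive
cycles in proportions 9:9:5; schedules D135/d135/D123/D12 in proportions
23:15:2:2 (assigned per patient); almost-daily sampling over 25–32-day
cycles with 10% dropout; multiplicative lognormal measurement noise
(σ = 0.15); BSA ~ N(1.78, 0.15²) m²; and a between-cycle carry-over
emulated by drawing each cycle's initial circulating count as
$B_0 = B\cdot$lognormal(CV 20%) while the marrow starts at $B_{bm}$.

The nominal patient (generator medians) is **B = 5.5 G/L, slope = 5.2,
k_tr = 0.19/day, γ = 0.45**, truth model M10. These were calibrated once,
against the clinically familiar D135 picture — nadir ≈ 0.3 G/L,
recovery above 1 G/L ≈ 23–24 days after the first dose, ≈ 13 leukopenic
days, and a D135−D123 recovery-time separation of ≈ 3.6 days under M10
versus ≈ 1.2 under M5 — and then frozen. B sits at the lower end of the
normal range (baselines in this population run ~2 G/L below healthy
values); k_tr = 0.19/day corresponds to a corrected mean maturation time
$n/k_{tr} \approx 126$ h for the single-transit models, in the plausible
range for chemotherapy-accelerated maturation; γ is roughly 2–3× typical
three-transit-model values, as expected when the chain is collapsed to one
compartment.

What the generator does **not** emulate: real interruptions and dose
modifications, G-CSF rescue, transfusion-triggered sampling, leukemic
regrowth, or model misspecification (cycles are generated by one of the
M1–M12 family). Passing recovery and discrimination tests on this cohort
therefore demonstrates that the estimation and study machinery is
self-consistent under realistic noise and sampling — not that any variant
is the true model of clinical data.

`gen_pk_concentration_data()` plays the same role for the PK side, with a
Kern-style design (`kern_sampling_schedule()`: 3 g/m² q12h on days 1, 2,
8, 9; 86 samples across days 1 and 8).

## Numerical choices

* WBC ODEs: `deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$;
  integration restarts at every dose-event boundary so the infusion on/off
  discontinuities are handled exactly. The PK forcing inside the WBC
  right-hand side is the exact closed form, not an interpolant.
* Feedback denominators ($x_{ma}$, and $0.01x_{pr}+0.99x_{tr}$ for
  M11/M12) are floored at $10^{-12}$ to survive transient deep
  suppression; trajectories more negative than $-10^{-9}$ abort.
* Zero-duration dose events are rejected; overlapping infusions sum their
  rates.
* Model predictions are floored at $10^{-8}$ G/L before taking logs in the
  residual; a failed simulation inside the optimiser returns a large
  constant residual (flagged) instead of crashing the fit.
* Washout and threshold crossings are located by fine grid search plus
  root bracketing on the exact PK solution / linear interpolation on the
  dense PD grid.

## Problem sizes in the test suite

The suite favours one moderately sized, seeded experiment per claim: a
40-cycle D135 recovery study under M5 (median absolute relative error of
every core parameter < 15%), a 16-cycle M10-truth cohort personalised
under both M5 and M10 for the noise-floor RMSE and schedule-separation
checks, 100–200-draw Monte-Carlo bands, 500–2000-draw IIV spread checks,
and single-start fits from the data-informed start for study-scale runs.

## Known limitations

* No mixed-effects (population) estimation — personalisation is by
  per-cycle/per-patient point estimation only, as is the Monte-Carlo
  uncertainty (variance–covariance of the individual fit, no shrinkage).
* The PK model carries no inter-individual variability of its own; IIV
  enters only as the constructed lognormal study in `iiv_study()`.
* No G-CSF dynamics, no leukemic-cell compartment, no linear or
  (sigmoid) E_max PD alternatives.
* The NONMEM dialect reader supports exactly the nine-column observation/
  dose grammar described in `?read_nonmem` (no control streams, no ADDL/SS
  expansion); BSA is not representable in the dialect and must be supplied
  at read time.
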