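---
title: "Predicting finite-dose percutaneous absorption from membrane permeation parameters"
author: "findose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting finite-dose percutaneous absorption from membrane permeation parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(findose)
```

## The problem

Safety assessment of cosmetics and dermopharmaceuticals needs the
*percutaneous absorption ratio*: the fraction of a small, in-use-like
applied dose (here 10 µL/cm² of aqueous solution) that crosses the stratum
corneum (SC) within 24 h. Classical in vitro permeation experiments
measure the *infinite-dose* steady state instead, where the donor never
depletes and the vehicle never dries. Under in-use conditions both effects
dominate: the applied amount is tiny, and an aqueous vehicle evaporates
completely within a couple of hours, after which chemical stranded on the
dry skin surface stops penetrating.

`findose` implements a closed-form, two-phase compartment model based on
Fick's first law that bridges the two regimes: permeation parameters are
estimated from ordinary infinite-dose Franz-cell profiles (using skin or a
synthetic membrane such as Strat-M), the vehicle's complete-evaporation
time is estimated from solution-weight measurements, and the finite-dose
absorption ratio follows analytically.

## Permeation parameters from infinite-dose profiles

A cumulative permeation profile $Q(t)$ (µg/cm²) through a membrane of
thickness $L$ becomes linear once steady state is reached. The fitted
tangent gives the steady-state flux (slope) and the lag time (x-axis
intercept), from which the three transport parameters follow:

$$\mathrm{Flux} = K_p C_v, \qquad D = \frac{L^2}{6\,T_{lag}}, \qquad
  K = \frac{6\,T_{lag} K_p}{L},$$

with $C_v$ the donor concentration (µg/mL), $K_p$ (cm/h) the permeability
coefficient, $D$ (cm²/h) the diffusion coefficient in the membrane and $K$
(dimensionless) the membrane/vehicle partition coefficient. These satisfy
$K_p = K D / L$ identically; `fit_permeation()` asserts the identity on
every fit.

Choices that matter:

* **Steady-state window.** The tangent is meaningful only over the linear
  part of the profile. Defaults: all points at $t \ge 2$ h for skin-like
  membranes, $t \ge 4$ h for Strat-M (whose 2-h point typically still sits
  in the transient). The window is an explicit argument because linearity
  is ultimately judged by looking at the profile.
* **Withdrawal correction.** When 500 µL aliquots are withdrawn from an
  8 mL receiver and replaced with fresh solvent, about 6 % of the receiver
  content leaves at each sampling.
  `correct_cumulative_for_sampling()` applies the mass balance
  $Q_n = (C_n V_{rec} + \sum_{i<n} C_i V_a)/A$. Profiles supplied as
  receiver concentrations are corrected on ingest; profiles supplied as
  cumulative amounts are taken as-is, so the correction is effectively a
  toggle controlled by which column the data provides.
* **Negative lag times** (possible on noisy profiles) are retained and
  flagged with a warning rather than clamped to zero: silently clamping
  would hide a bad fit, whereas a propagated negative $K$ and undefined
  $D$ are immediately visible.
* **Replicates.** Parameters are estimated per Franz cell and aggregated
  as mean ± standard error (`summarize_replicates()`), the conventional
  presentation for $n = 3\!-\!4$ cells.

**Validity.** The lag-time method presumes the experiment reaches steady
state. With sampling to 8 h this requires roughly $T_{lag} \le 1$ h
($T_{lag} = L K / 6 K_p$); there the package recovers noiseless ground
truth to better than 2 % in $K_p$ and 5 % in $K$ and $D$. For slowly
equilibrating combinations (large $K L / K_p$) the tangent of an 8-h
profile underestimates the flux by construction — no window choice can
rescue an experiment that never reached steady state, and the package
makes no recovery claim there.

## The two-phase finite-dose model

An applied dose $M_0 = V_{dose} C_v$ sits on the skin in a vehicle volume
$V$ above an SC of volume $V_{sc}$ and area $A$.

**Phase 1 ($0 \le t \le T_{eva}$):** vehicle still present. Surface
solution and SC are pooled into one well-mixed compartment of volume
$V + V_{sc}$, cleared first-order through the SC:

$$M_{sur+SC}(t) = M_0\, e^{-K_p A t/(V+V_{sc})},\qquad
  M_1 = M_0\left(1 - e^{-K_p A T_{eva}/(V+V_{sc})}\right).$$

**Partition split at $T_{eva}$:** the vehicle is gone; the remaining
amount divides between an inert surface residue and the SC depot by the
$K$-weighted volume fraction $V_{sc}K/(V + V_{sc}K)$.

**Phase 2 ($T_{eva} < t \le t_{end}$):** only the SC depot keeps clearing,
with rate $K_p A / V_{sc}$:

$$M_2 = M_0\,\frac{V_{sc}K}{V+V_{sc}K}\,
   e^{-K_p A T_{eva}/(V+V_{sc})}
   \left(1 - e^{-K_p A (t_{end}-T_{eva})/V_{sc}}\right).$$

The percutaneous absorption is $M_1 + M_2$ and the absorption ratio
$(M_1+M_2)/M_0$. The four output components satisfy
$M_1 + M_2 + M_{SC}(t_{end}) + \text{surface residue} = M_0$ exactly.

Model assumptions, stated plainly:

* $V$ is held constant throughout phase 1 even though the vehicle is
  evaporating; the model switches abruptly at $T_{eva}$. This is the
  simplification that makes the closed form possible, and it is a known
  limitation for vehicles whose concentration rises steeply before
  dry-down.
* Chemical left on the surface after $T_{eva}$ never penetrates
  (precipitated, no carrier). It is reported as `surface_residue` rather
  than dropped, so the unabsorbed mass is visible.
* Two deliberate literalisms of the model are worth knowing: phase 1
  pools solvent and SC with a $K$-free concentration $M/(V+V_{sc})$ while
  the split at $T_{eva}$ is $K$-weighted, which is thermodynamically
  inconsistent for $K \ne 1$; and phase 2 applies $K_p$ (which already
  embeds $K$) to the SC concentration $M_{SC}/V_{sc}$. Both are
  implemented exactly as the model defines them; re-deriving a fully
  consistent variant would be a different model with different parameter
  requirements.

### Default constants

| constant | default | meaning |
|---|---|---|
| `A` | 1.0 cm² | application area |
| `V` | 0.01 cm³ | vehicle volume (10 µL dose) |
| `Vsc` | 0.002 cm³ | SC volume under 1 cm² |
| `dose_volume` | 0.01 cm³ | converts $C_v$ to $M_0$ |
| `Teva` | 1.5 h | complete evaporation of a 10-µL aqueous dose |
| `t_end` | 24 h | end of exposure |
| `L` | 0.10 cm (skin), 0.03 cm (Strat-M) | membrane thickness |

`t_end` is configurable because 24 h is an experiment duration, not a
model constant; the phase-2 formulas use $t_{end}$ wherever a literal 24
would otherwise appear.

## Estimating the evaporation time

`estimate_teva()` scans an applied-solution weight series (weighed every
0.25 h until stable) for a sustained plateau: a consecutive change
qualifies when it is at most 1 % of the initial weight (the criterion is
relative, so rescaling the series changes nothing), and $T_{eva}$ is the
earliest time after which every change qualifies — the end of the last
significant weight drop. The plateau must persist to the end of the
series; a still-declining series raises an "evaporation incomplete"
error rather than returning a guess. The 1 % threshold is a design choice
calibrated so that a 10-µL aqueous dose drying linearly to its
non-volatile residue in 1.5 h is scored at exactly 1.5 h; a looser
threshold can only move the estimate earlier.

## What the synthetic data emulates — and what it does not

The generators exist so every estimator in the package can be tested
against known ground truth:

* `simulate_permeation_profile()` draws from the exact slab-diffusion
  series solution
  $Q(t) = K L C_v\,(Dt/L^2 - 1/6 - (2/\pi^2)\sum_n ((-1)^n/n^2)
  e^{-Dn^2\pi^2 t/L^2})$, whose large-$t$ tangent has slope $K_p C_v$ and
  intercept $L^2/6D$ — so lag-time estimation is exercised against the
  physics it presumes, not against its own asymptote. The series is
  truncated at terms below 1e-12 (cap 200) and floored at 0 against
  round-off near $t = 0$.
* `simulate_evaporation_series()` produces a linear decline to a 1 %
  residual plateau with a few confirming measurements.
* `simulate_observed_absorption()` perturbs the *numerically integrated*
  ratio (independent of the closed-form path) with multiplicative
  Gaussian noise, clipped to [0, 1]. Multiplicative noise was chosen
  because measured amounts are positive and replicate scatter roughly
  scales with the mean.

Real data differ in ways the generators deliberately do not model:
biological between-skin variability with structure (follicle density,
thickness variation), metabolism in viable tissue, evaporation kinetics
that flatten gradually rather than piecewise-linearly, and non-Gaussian
analytical error. Passing round-trip tests therefore demonstrates
correctness of the estimators under the model's own physics, not
predictive accuracy on any particular skin lot.

## Numerical choices

* The closed forms are verified against an independent fixed-step
  classical RK4 integration (`ode_absorption()`, via deSolve) of the two
  clearance ODEs with the partition split applied at $T_{eva}$; 10,000
  steps per phase by default, chosen for determinism (the system is
  linear and non-stiff). Agreement is better than 1e-6 relative across a
  wide parameter grid; tests assert it.
* Exponents like $K_p A (t_{end}-T_{eva})/V_{sc}$ can exceed several
  hundred; `exp()` then underflows cleanly to 0, which is the correct
  physical limit (complete clearance), so no log-space rearrangement is
  needed. A side effect: once these factors saturate, totals for very
  large $K_p$ become bit-identical although mathematically strictly
  increasing; monotonicity checks treat that saturation explicitly.
* A fitted slope at or below 1e-10 of the data scale is reported as "no
  positive steady-state flux" rather than producing an absurd lag time
  from QR round-off on flat data.
* $K = \infty$ is accepted and handled exactly (partition fraction 1,
  zero surface residue), serving as the boundary case of the partition
  split.

## Applicability domain

Synthetic-membrane-derived parameters stand in for skin only where the
two membranes behave alike. For Strat-M that holds for chemicals with
$-0.2 \le \log K_{ow} \le 2.0$; hydrophilic chemicals permeate skin
largely through appendages that a polymer membrane lacks.
`reproduce_study()` therefore emits Strat-M-based predictions only inside
this domain by default, and outside it only when explicitly requested,
flagged and with a warning.

## Worked pipeline

```{r pipeline, eval = FALSE}
# 1. permeation parameters from an infinite-dose profile
prof <- simulate_permeation_profile(Kp = 1.23e-3, K = 0.422, Cv = 1e4,
                                    membrane = membrane_spec("strat_m", 0.03),
                                    times = c(2, 4, 6, 8))
fit <- fit_permeation(prof)

# 2. evaporation time from a weight series
teva <- estimate_teva(simulate_evaporation_series(w0 = 10, Teva_true = 1.5))

# 3. finite-dose absorption ratio
cfg <- finite_dose_config(Teva = teva$Teva)
predict_absorption(fit, cfg = cfg)
```

Problem sizes used throughout the test-suite and verification runs —
5×5×5 parameter grids for the closed-form/integrator agreement, 200
replicate draws for noise studies, 10,000 integrator steps per phase —
were chosen as the smallest sizes at which the asserted tolerances are
meaningful for a 4th-order integrator and Monte-Carlo medians stabilise.

## Known limitations

* Constant-$V$ phase 1 and the abrupt switch at $T_{eva}$ (above).
* Single SC barrier: no viable-epidermis/dermis compartment, hence no
  prediction of amounts retained in deeper tissue; parameters for such a
  layer cannot be obtained from a synthetic membrane anyway.
* Aqueous vehicles only: formulation effects (polyols, surfactants,
  penetration enhancers) change $K_p$ and $K$ during dry-down and are out
  of scope.
* Single application; no multi-dose regimens.
* The lag-time method's steady-state requirement bounds which parameter
  combinations are estimable from an 8-h experiment (see above).
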