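---
title: "Modelling winter carbohydrate dynamics and frost hardiness in walnut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter carbohydrate dynamics and frost hardiness in walnut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wintercarb)
```

## The problem

Deciduous trees in frost-exposed climates survive winter by converting starch
reserves into soluble sugars — in walnut, glucose + fructose + sucrose (GFS),
which make up about 90% of the soluble pool. Sugar concentration per unit
tissue water depresses the freezing point and drives cold acclimation, so the
seasonal starch–sugar balance largely determines frost hardiness (FH, the
highest temperature inducing frost damage; more negative = hardier).
`wintercarb` implements a daily process-based model of this interconversion
over the leafless period, its calibration machinery, and the downstream
osmo-hydric frost-hardiness predictor, together with a synthetic-data
generator that emulates the two kinds of experiments the model is built on:
multi-year monthly orchard monitoring and constant-temperature storage of
detached branches.

## Dormancy phenology

Enzymatic activity depends on the dormancy stage. The model assumes a
sequential transition: endodormancy is released by accumulated chilling units
(CU), computed daily from mean air temperature with the inverse Richardson
function — zero above `t_high` = 26.7 °C, saturating at
`t_high − t_low` = 23.6 CU/day below `t_low` = 3.1 °C. Once CU reaches
`cu_crit` = 2298.8, forcing units (FU) accumulate as a sigmoid of daily mean
temperature (midpoint `t50` = 13.46 °C, slope 0.244 °C⁻¹); budburst occurs at
`fu_crit` = 21.2. The phenological stage index is

PS = min(CU/CU~crit~, 1) + min(FU/FU~crit~, 1) ∈ [0, 2],

with PS = 1 exactly at the endo→eco transition. Two conventions worth noting:
the sigmoid slope is taken positive (+0.244) so that forcing increases with
temperature — the biologically required direction — and `t50` is used at its
full precision of 13.46 °C. CU is capped at `cu_crit` inside the PS formula
only; the raw cumulative sum is kept in the output for diagnostics. Chilling
accumulation starts on the first day of the series with day-of-year 244
(about 1 September), and seasons spanning a year boundary are handled by
calendar arithmetic, so leap years need no special care.

## Kinetics

Each of three reactions — cold-optimum starch hydrolysis (k~1c~), mild-optimum
hydrolysis (k~1m~) and starch re-synthesis (k~2~) — follows

k(θ, PS) = max[0, (a·PS + b) · exp(−(θ − μ)² / (σ·2π))],

a symmetric Gaussian in temperature with optimum μ, modulated linearly by
stage. The Gaussian denominator is written σ·2π rather than the classical
2σ²; because σ is a free fitted width the functional family is identical and
only the numerical interpretation of σ changes. To keep the rate continuous
at the endo→eco transition the stage coefficients are parameterised by the
transition rate `k_trans` and branch differences `d_endo`, `d_eco`:

a = (k_trans + d)/2, b = (k_trans − d)/2,

so a + b = k_trans in both branches (the eco branch uses the minus sign in b,
which the constraint a + b = k_trans forces). At PS exactly 1 the eco branch
is used; continuity makes the choice immaterial.

Respiration is zero-order in substrate:

R = R~max~ / (1 + exp(a₃·(WC − b₃))) · Q₁₀^((θ − 15)/10),

a logistic function of water content WC times a Q₁₀ temperature factor. With
a₃ < 0 respiration increases with WC, matching the observation that
well-hydrated branches lose carbon faster in warm conditions.

## The three model variants

The daily update of the two pools (mg per g dry matter) comes in three forms
along an empirical→mechanistic continuum, all closing the starch balance with
`Starch(t+1) = Starch(t) − ΔGFS − R`, so total non-structural carbohydrate
(NSC = GFS + starch) declines by exactly R per day:

* **simple** — zero-order: H = k₁c + k₁m, S = k₂ (rates in mg·g DM⁻¹·day⁻¹);
* **intermediate** — substrate-limited: H = (k₁c + k₁m)·Starch, S = k₂·GFS
  (rates in day⁻¹);
* **complete** — Michaelis–Menten: each flux is v·[S]/(K~M~ + [S]) with the
  maximal velocity v following the same temperature×stage law.

This gives 19 free parameters for the first two variants and 22 for the
complete one. Note the literal reading of the update equations: the −R term
appears in both pool updates but cancels in the starch balance, so NSC
declines by R (not 2R) per day; the mass-balance tests assert exactly this.

The model equations do not say what happens when a flux would overdraw a
pool, which zero-order terms can do. The package's rule: the starch outflow H
is capped at the available starch; then the GFS outflows S + R are rescaled
by (GFS + H)/(S + R) if they exceed what the pool plus the day's inflow can
supply. This preserves nonnegativity and the mass balance, and every floored
day is flagged in the trajectory; the realized (possibly reduced) respiration
is reported alongside.

Water content is not modelled: it is linearly interpolated between
observations (held constant, with a warning, outside the observed span),
as branch WC is treated as a measured input throughout.

## Calibration

Parameters are fitted by minimising the pooled residual sum of squares of
simulated vs. observed GFS and starch (equal weights) with Nelder–Mead
restarted from a Latin hypercube sample of the bound box. Bounds are enforced
through a smooth elementwise logit map to the real line, avoiding the
non-smoothness a penalty would introduce. Each start is polished by
restarting the simplex from its own endpoint until the relative improvement
drops below `rel_tol` (default 10⁻⁸) or the per-start evaluation budget
(default 200,000, read as a per-start figure) is exhausted; the best endpoint
across starts wins. The default box brackets the biologically established
optima: μ₁c ∈ [−5, 5] °C, μ₁m ∈ [10, 25] °C, μ₂ ∈ [8, 20] °C, Q₁₀ ∈ [1, 4],
a₃ ∈ [−50, 0], b₃ ∈ [0.3, 1.5], σ ∈ (0.5, 500], with rate magnitudes scaled
per variant's units. Calibration and validation datasets are kept separate;
`metric_report()` labels metrics RMSE on calibration data and RMSEP on
held-out data, with Nash–Sutcliffe efficiency Eff = (SS~tot~ − SS~res~)/SS~tot~
alongside.

## Frost hardiness

The osmo-hydric relation FH = a·ln(GFS)/WC + b is linear in ln(GFS)/WC, so
its calibration is ordinary least squares (estimator choice: OLS, the
standard reading when nothing else is stated); defaults a = −5.32 °C and
b = 1.71 °C are the published branch coefficients. Prediction uses observed,
interpolated WC — not a modelled one — so the coupled chain
carbon model → FH only propagates uncertainty through GFS.

## The synthetic-data generator

No field data ship with the package; the generator defines the study
conditions everything is tested under:

* **Weather** — daily mean temperature is a seasonal sinusoid (annual mean
  11 °C, half-amplitude 8 °C, warmest mid-July) plus AR(1) noise (marginal
  SD 3 °C, lag-1 autocorrelation 0.7), with tmin/tmax at ∓ half an 8 °C
  diurnal range. These values are a realistic mid-elevation central-France
  orchard climate; a 300-day series from late August comfortably spans one
  leafless season (budburst typically falls in April).
* **Field campaign** — one latent branch trajectory simulated under known
  true parameters, destructively sampled every 30 days with independent
  Gaussian noise (SD 5 mg·g DM⁻¹ on each pool, 0.03 g·g⁻¹ on WC, 1 °C on
  FH). WC follows a piecewise-linear seasonal profile (0.85 → 0.70 →
  0.75 → 0.95) because the field treats WC as observed, not modelled.
* **Ground truth** — μ₁c = −0.1 °C, μ₁m = 17 °C, μ₂ = 13 °C (inside the
  established ranges for the three activities), Q₁₀ = 2.64, a₃ = −10,
  b₃ = 0.8, R~max~ = 0.3 mg·g DM⁻¹·day⁻¹, and rate amplitudes chosen so the
  latent season reproduces the canonical pattern: starch falls and GFS rises
  into midwinter, then the trend reverses as re-synthesis strengthens during
  ecodormancy. Initial pools are 25 (GFS) and 90 (starch) mg·g DM⁻¹.
* **Controlled-conditions experiment** — branches "detached" from the latent
  trajectory on a sampling date are held at constant temperature (default
  grid −3, 1, 5, 10, 15, 20, 25 °C) for 7 and 20 days (the protocol's
  "19–21 days" fixed at 20); WC stays at its sampling-day value (cut ends
  sealed) while chilling/forcing continue to accumulate at the treatment
  temperature. Reported responses are per-day changes normalised by the
  opposite initial pool (ΔGFS/day over initial starch, and vice versa).
* **Depleted scenario** — the defoliation manipulation is represented purely
  as a reduced initial starch pool (default −60%), everything else equal.

What the generator does *not* emulate: tree-to-tree random effects
(replicates are i.i.d. noise around one latent trajectory), within-day
temperature dynamics, carbon input before leaf fall, and root export after
budburst. Passing recovery tests therefore demonstrate internal consistency
of the estimation machinery under the stated noise model, not performance on
real orchard data.

## Numerical choices and problem sizes

The daily state loop is a handful of scalar operations with all
temperature/stage-dependent rates precomputed, so one season simulates in
well under a millisecond and multistart calibration stays cheap. The test
suite and the acceptance script run the heavier protocols at reduced but
fixed sizes chosen as the package's own compromise between statistical power
and runtime: zero-noise self-consistency uses 20 starts with a 20,000
evaluation budget per start on one season; the three-season noisy recovery
uses 10 starts; the three-variant discrimination comparison uses 6 starts
and a 15,000-evaluation budget per start, calibrating on one normal and one
carbohydrate-depleted season and validating on a held-out normal season —
the depleted season matters, because substrate limitation only becomes
identifiable when seasons start from different pool sizes. The three-Gaussian decomposition of
treatment-response curves is a bounded Levenberg–Marquardt fit restarted
from a Latin hypercube of component placements; the two positive components
are reported ordered by optimum temperature (cold before mild), which
resolves the label-switching ambiguity.

## Known limitations

* With ~9 observations per season and 19 free parameters, the calibration
  is near the edge of identifiability: optima in μ can trade off against
  width and amplitude parameters under realistic observation noise. The
  recovery tests quantify this honestly rather than hiding it.
* On data generated by the substrate-limited variant, the Michaelis–Menten
  variant can approximately reproduce the same dynamics (large K~M~ with
  rescaled maximal velocities), so validation comparisons between those two
  variants are inherently close; only the zero-order variant separates
  cleanly. Discriminating the two mechanistic variants needs information
  the synthetic world does not contain, such as enzymes with genuinely
  different affinities.
* The Gaussian temperature response is symmetric by construction; real
  enzyme activities decay faster above the optimum.
* Respiration is zero-order in substrate and drawn from the GFS pool; at
  very low NSC the flooring rule, not the kinetics, governs the dynamics.
* The phenology constants are literature values for one walnut cultivar and
  are not refitted.
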