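---
title: "A multi-scale model of Achilles tendon remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of Achilles tendon remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonadapt)
```

## The model in one page

The Achilles tendon is represented as a population of `N` parallel collagen
"strings" that share material constants but differ in slack length `L_i`.
A fiber carries load only once the tendon's end-to-end length `x` exceeds
`L_i`; its force is linear in the extension with stiffness
`k_i = A_F E_T / L_i`, so the slack-length distribution produces the
tendon's toe region by sequential recruitment, and the whole-tendon
force-extension curve is piecewise linear, non-decreasing and convex.

Two damage processes remove fibers, and stochastic repair replaces them:

* **Mechanical fatigue.** A fiber's peak stress over a gait cycle is
  `sigma_i = E_T (x_peak - L_i)/L_i`; its fatigue life follows the linear
  S-N relation `sigma = a - b log10(n_fail)` (`a` = 100 MPa,
  `b` = 8.25 MPa per decade), and the probability that it has failed after
  `n` cycles is the exponential cumulative-failure function
  `P = -kappa + kappa exp(lambda n / n_fail)`, clamped to [0, 1]. The
  constants are pinned by three conditions (`P(0) = 0`, `P(n_fail/2) = 0.1`,
  `P(n_fail) = 1`), whose closed-form solution is `kappa = 1/80`,
  `lambda = 2 ln 9 = 4.394`. Short fibers are the most stressed, so fatigue
  eats the short tail of the length distribution.
* **Strain-shielded proteolysis.** Tensile strain protects collagen from
  enzymatic cleavage; once per day each fiber survives proteolysis with
  probability `1 - exp(-phi eps_i)` at its peak strain of the day
  (`phi` = 300, so fibers strained at or above ~1.5% are essentially fully
  shielded). Long, under-strained fibers are the most vulnerable, so
  proteolysis eats the long tail.

Failed fibers are always repaired, in place, from triangular distributions
of relative length change: fatigue repairs are biased toward lengthening
(default triangular(+0.25%, +0.75%, +1.25%)) and proteolytic repairs are
the mirror image, biased toward shortening. Fatigue removes short fibers
and puts them back longer; proteolysis removes long fibers and puts them
back shorter. Whichever process dominates, the whole distribution
"marches" in the corresponding direction, which is how the tendon changes
its mean length.

The loading comes from a three-component Hill-type Achilles-plantarflexor
model driven by one stride of walking (ankle torque and angle). Inverse
dynamics converts torque to tendon force through an angle-dependent moment
arm; inverting the recruitment curve gives the tendon length; the
constant-thickness pennation relation gives the muscle fiber length and
velocity; and the activation demanded to supply the force, together with a
four-term energetics model (activation heat, maintenance heat,
shortening/lengthening heat, mechanical work), gives a metabolic cost rate
whose time integral is the cost `Q` of the stride (J).

The whole-organism feedback is a single scalar: the activity factor
`beta = min(1, Q_min / Q)`, where `Q_min` is the minimum cost over a grid of
tendon geometries (mean length 250-280 mm, fiber SD 0.5-3 mm), computed
once at initialization with `beta = 1`. The daily 5,000 load cycles are
applied in three equal blocks at torque `beta * tau_measured`; `beta` is
refreshed from the current geometry's cost after each block. An expensive
geometry is therefore loaded gently (low strain, heavy proteolysis,
shortening) and an economical one is loaded hard (high strain, fatigue,
lengthening), which is what drives the geometry toward a stable
equilibrium near the cost minimum.

## Interpretation choices

Three points the formulation leaves open were resolved as follows.

**What `Q` means in the feedback.** The cost ratio is evaluated for the
*measured* (unscaled) gait at the current geometry, making `beta` a pure
function of geometry. The alternative - feeding the `beta`-scaled cost
back into the ratio - makes the block-to-block update
`beta_{k+1} = Q_min / Q(beta_k)`, which is a divergent two-cycle whenever
`Q` grows roughly linearly in `beta`; the geometry-function reading is
stable and matches the way the cost-ratio map is presented as a function
of tendon geometry.

**Metabolic cost of infeasible demands.** The reported activation is
clamped to [0, 1], but the heat terms scale with the unclamped activation
*demand* `F_M / (F_L F_V F_max)`. When the required force exceeds the
muscle's instantaneous capacity the metabolic demand of meeting it (through
synergist recruitment and inefficient operation) keeps growing; without
this, clamping silently capped the cost exactly at the geometries that
should be expensive, and the cost surface lost the structure that the
stability analysis needs. For the same reason the muscle's projected length
is floored at 1 mm inside the gait-cost evaluation: a tendon long enough to
crowd out the muscle shows up as an enormous finite cost rather than an
error.

**Constant-load demonstrations.** The damage/repair demonstrations hold
the daily *peak extension* constant (5.5% tendon strain, i.e. 55 MPa mean
fiber stress at `E_T` = 1 GPa). Under constant extension there is no load
redistribution, so without repair the failure front through the short tail
slows down as it advances into denser parts of the length distribution;
under constant force the same scenario is a rupture cascade within days.
Proteolysis-only demonstrations use a lighter load (~1.5% peak-fiber
strain) because at 5.5% strain every fiber in a realistic population is
fully shielded.

## Parameters

Tendon and damage constants (fiber count 100,000; fiber area
6.15e-4 mm^2; tendon area 60 mm^2; `E_T` 1 GPa; `a` 100 MPa; `b` 8.25;
`kappa` 1/80; `lambda` 2 ln 9; `phi` 300; 5,000 cycles/day; peak torque
165 N.m) are the published Achilles values and live in
`default_config()`.

The musculotendon and energetics constants are not derivable from the
tendon model and are the package's own literature-scale choices, all
config-exposed:

* `f_max` 6500 N, `l_opt` 50 mm, `v_max` 10 `l_opt`/s, pennation 25
  degrees: a lumped plantarflexor contractile element. The torque share is
  1 because the Achilles tendon transmits the full plantarflexor torque;
  165 N.m over a ~50-60 mm moment arm and 60 mm^2 of tendon reproduces the
  ~55 MPa peak operating stress of normal walking.
* moment arm `r(theta) = L_calc (1 + 0.1 theta)` with `L_calc` 60 mm;
  musculotendon path length 312 mm at the neutral angle, chosen so the
  muscle operates near `l_opt` when the tendon geometry is in the middle
  of the explored domain.
* force-length width 0.22, force-velocity curvature 0.25 with eccentric
  plateau 1.45; heat coefficients `h_am` 60 W/kg (40/60
  activation/maintenance split) and shortening heat 200 W/kg at `v_max`,
  with muscle mass derived from `f_max`, a 0.25 MPa specific tension and
  1059.7 kg/m^3 density. These magnitudes put the heat terms on the same
  footing as the mechanical work term (overall efficiency in the
  physiological 25-50% range); much smaller heat coefficients flatten the
  cost surface and remove the equilibrium structure.

With these defaults the cost surface over the geometry domain is U-shaped
in mean length with its minimum near 262 mm, an unstable balance point
near 254 mm (shorter tendons diverge: cost and proteolysis grow together)
and a stable equilibrium near 266 mm where the expected daily fatigue and
proteolysis rates cross.

**Repair distributions.** The repair *means* (+0.75%/-0.75%, mirror
images) set how fast the distribution marches; the repair *spreads* set
the fiber-length dispersion re-injected per repair and hence the
equilibrium SD. Because both damage processes are exponential in strain,
dispersion multiplies their equilibrium rates by roughly
`exp((lambda_eff SD)^2 / 2)`; century-scale equilibrium turnover requires
an equilibrium SD below about 1 mm, which the default symmetric +-0.5%
spreads produce. Dispersion equilibrates far more slowly than mean length,
so the default initial geometry (mean 266 mm, SD 0.6 mm) is set at the
equilibrium scale.

## The synthetic gait cycle

The measured stride behind the model is not deposited, so
`make_walking_cycle()` synthesizes one: a smooth torque bump over the
stance phase (60% of a 1.1 s stride) peaking at 165 N.m at 45% of the
stride, and an ankle angle waveform with the phasing of normal walking -
progressive dorsiflexion under rising torque (the loaded tendon stretches
and stores energy) reversing into a push-off plantarflexion at toe-off
(amplitude 0.35 rad). The phasing matters: a generic sinusoid feeds ~70 J
of net positive joint work into every stride, which swamps the heat terms
and removes the geometry sensitivity of the cost. The surrogate reproduces
plausible magnitudes and phasing, not any specific subject; all downstream
quantitative results inherit it, which is the main reason equilibrium
turnover times are order-of-magnitude rather than exact reproductions.

## Numerical choices

* The force-extension curve is evaluated and inverted exactly on its
  piecewise-linear segments (sorted slack lengths with cumulative
  stiffness sums); no iterative root finding is involved, and a bisection
  oracle in the test suite confirms the inversion to < 1e-6 mm.
* Fewer fibers than the physical 100,000 may be simulated; the per-fiber
  area is then scaled (`scaled_fiber_area()`) so the total cross-section
  and force-extension behavior are preserved. Stress, strain and damage
  probabilities are per-fiber quantities independent of area, so the
  distribution dynamics are N-invariant in expectation and turnover times
  are N-invariant by construction. Simulations in the tests and the
  acceptance script use 10^3-10^4 fibers and 120-720 days; the cost-surface
  sweep uses 2,000-fiber idealized (quantile-spaced) populations.
* Initial Gaussian draws are resampled, never clipped, if non-positive.
* The daily 5,000 cycles split as 1667/1667/1666; draw order within a day
  is fixed (fatigue blocks in order, proteolysis, fatigue repairs,
  proteolytic repairs) so runs are bit-reproducible per seed.
* Failure probability per block uses that block's cycle count only; no
  fatigue memory is carried across days for surviving fibers, since the
  daily repair cycle restores all failures and the per-day restatement of
  the failure function leaves partial-damage bookkeeping unspecified.
* Turnover accounting counts whole-fiber lengths (removed = pre-damage
  length, synthesized = repaired length); a `segment` option counts only
  net length changes instead.
* `beta` is clamped above at 1 (an off-grid geometry can undercut the
  gridded minimum) and has no lower clamp (the ratio cannot reach 0).
* A zero-torque day is a degenerate but well-defined input: every fiber is
  unstrained, proteolysis removes all of them (`e^0 = 1`), and repair
  restores the count.

## What the simulations do and do not show

The equilibrium turnover times (~1 century at 5,000 cycles/day, longer at
2,000, with the transient dip below 5 years when a long tendon shortens
home) emerge from the damage balance, not from any turnover calibration.
They depend on the surrogate gait and the unprinted muscle constants, so
they are order-of-magnitude results; the *ratio* between the 2,000- and
5,000-cycle turnover times is much better determined (~1.5) because the
gait dependence largely cancels.

Two dynamical features differ visibly from the source system. First, with
this cost surface the interior of the convergent domain is
quasi-stationary: damage rates there are ~1e-5 per fiber per day, so an
interior start barely moves in 720 days, and convergence is visible mainly
from the steep long flank. Second, fiber dispersion relaxes much more
slowly than mean length, so 720-day runs probe the dispersion they were
started with. Both are consequences of the exponential strain dependence
of the damage laws combined with a moderately sloped cost valley; a
sharper valley (different gait or muscle constants) accelerates both.

The model deliberately excludes muscle adaptation, inflammation and
disease states, kink-mode (generalized) fibril damage, non-uniform
stiffness along the tendon, time-dependent enzyme binding kinetics, and
any re-optimization of the gait pattern itself.

## Reduced problem sizes

The test suite runs populations of 500-4,000 fibers for 10-500 days, and
the acceptance script runs 10^4 fibers for 720 days; these sizes keep the
full suite in the minutes range while staying in the N-invariant regime
discussed above.
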