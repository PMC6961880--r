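---
title: "Modelling histamine dynamics and wheal formation in urticaria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling histamine dynamics and wheal formation in urticaria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whealdyn)
```

## The model

Urticaria presents as transient skin wheals whose shapes — rings, broken
rings, discs, scattered dots, confluent rashes — vary strikingly between
patients.  `whealdyn` simulates a deliberately minimal model of the process:
a single diffusing species $u(\mathbf{x}, t)$, the dermal histamine
concentration, obeying

$$\frac{\partial u}{\partial t} = D_u \nabla^2 u
  + \gamma\, u\, \chi(U) - \frac{\alpha_2 u}{\alpha_1 + u^2}
  + \mu - \alpha_0 u$$

on the unit square with zero-flux boundaries (the skin is a closed system at
this scale).  The four reaction terms are:

* **Self-activation** $\gamma u \chi(U)$.  Histamine released by mast cells
  stimulates neighbouring mast cells to degranulate in turn.  Each cell holds
  a finite store: $U(\mathbf{x},t) = \int_0^t \gamma u\, dt$ accumulates the
  released amount, and the switch $\chi$ drops from 1 to 0 — permanently,
  since the model ignores resynthesis — once $U$ exceeds the store size
  $U_{tot}$.
* **Self-inhibition** $\alpha_2 u / (\alpha_1 + u^2)$.  Mediators co-released
  with histamine suppress further release.  The effect peaks at concentration
  $u = \sqrt{\alpha_1}$ and wanes at higher $u$; $\alpha_2$ sets its maximal
  strength.  This non-monotone inhibition is what converts a spatially
  uniform activation into patterned output.
* **Basal secretion** $\mu$ and **basal decay** $\alpha_0 u$.

The visible wheal is a readout, not a dynamic variable:
$H(u) = 1/(1 + e^{-\beta (u - u_r)})$ with threshold $u_r$ and a steepness
$\beta$ that depends on the direction of motion — shallower while $u$ rises
(`beta_rise = 30`) than while it falls (`beta_fall = 150`), because skin
recovers from a wheal more slowly than the wheal appears.  Masks are
binarized at $H \ge 0.5$.

All simulations run in dimensionless variables; the default scales
(`scaleSet()`) map the unit square to a 27.4 cm skin patch and one time unit
to 250 s, and `speedToDimensional()` converts front speeds to mm/hr.  The
default kinetic values (`kineticParams()`: $\gamma = 4$, $\alpha_0 = 0.7$,
$\alpha_1 = 0.4$, $\alpha_2 = 4.5$, $\mu = 1.5$, $U_{tot} = 150$,
$D_u = 4.7\times 10^{-6}$) are the representative set used throughout the
package; the printed dimensional/dimensionless rate ratios of the source
parameter table are mutually inconsistent (500, 250 and 25 across rows), so
the package deliberately works in the dimensionless column only and converts
nothing but length, time and speed.

## Space-free structure

With $\chi = 1$ the homogeneous steady states solve a cubic; `equilibria()`
returns them with linear-stability labels:

```{r}
p <- kineticParams()
equilibria(p)
```

The low stable state $u_0^*$ is healthy skin; the unstable state $u_l^*$ is
the ignition threshold: a perturbation that lifts a sufficiently large region
above $u_l^*$ grows without bound (there is no upper equilibrium — growth is
arrested only by store depletion), while smaller perturbations relax back.
Two structural results anchor the phase diagram: wheals are impossible when
$\gamma - \alpha_0 < 0$ (`noPatternCondition()`), and with $\alpha_2 = 0$ the
equation is linear so development, when it occurs, is spatially uniform —
the "anaphylactic" regime rather than a patterned one.

For a front invading the *unstable* state the classical linear-spreading
bound applies, implemented as `waveSpeedBound()`:
$c \ge 2\sqrt{D_u(\gamma - g'(u_l^*) - \alpha_0)}$ with $g$ the inhibition
term.  At the default parameters this evaluates to $7.8\times10^{-3}$
(dimensionless), about 30 mm/hr.

## Stimuli and the minimal developing stimulus

The initial condition perturbs the healthy state:
$u(\mathbf{x},0) = u_0^* + r(\phi + s\psi)/(1+s)$, with $\phi$ an i.i.d.
uniform $[0,1]$ field (one draw per grid cell, seeded — the field is
resolution-dependent by construction, so outputs record both seed and grid
size) and $\psi = (\cos(n\pi x)\cos(m\pi y)+1)/2$ a long-range weight.
`findPMin()` bisects the stimulus magnitude $r$ for the smallest stimulus
that develops a wheal, reported as a percentage $P_r = 100\,r/c_{max}$ of a
reference concentration ($c_{max} = 1$ by default; the reference is a free
normalization, so only relative trends in $P_{min}$ are meaningful).
"Develops" means $\max_\mathbf{x} u > u_r$ at some time after a burn-in of 1
time unit; the burn-in exists because the stimulus itself may exceed $u_r$
pointwise before the dynamics decide anything.  The bisection runs at a
fixed seed (1% relative tolerance), making the search deterministic.

The wheal threshold $u_r$ for simulations defaults to 0.4, between $u_0^*
\approx 0.224$ and $u_l^* \approx 0.623$: healthy skin must not count as
wheal, and any level strictly between the two equilibria crosses the same
moving front, so the measured front position is insensitive to the exact
choice.

## Numerics

The solver is explicit Euler with the 5-point Laplacian and mirrored ghost
cells (`rdRun()`, compiled core), plus an axisymmetric finite-volume
reduction on $r \in [0, 1/2]$ (`radial_mode`) whose cell faces make the
zero-flux condition exact at the axis and the rim.  Design notes:

* Step size: automatic `dt` takes 40% of the diffusive stability limit and
  caps $dt \cdot (\gamma + \alpha_0 + \alpha_2/\alpha_1)$ at 0.05; a
  configured `dt` above the CFL limit is an error, an aggressive kinetic
  step only a warning.  Because ignition grows like $e^{(\gamma-\alpha_0)t}$,
  Euler error through the growth phase is amplified roughly linearly in
  $dt$; the dt-halving convergence test therefore runs at $dt = 5\times
  10^{-5}$.
* The cumulative release integral uses the rectangle rule at the pre-step
  concentration; $\chi$ switches off at most once per cell.
* The rising/falling memory per cell is the sign of the last nonzero change
  of $u$, initialized to rising.
* Front tracking (`trackFront()`) takes the outermost crossing of $u = u_r$
  (linear interpolation), on $\ge 32$ rays with bilinear sampling in 2-D;
  the expansion speed is the least-squares slope over the longest window
  whose linear-fit residuals stay below 5% of the radius range.
* Pattern runs default to a 512-cell grid; front-speed measurements default
  to the radial reduction at 1024–4096 points because the front is a few
  times $10^{-3}$ of the domain wide and 2-D grids of affordable size
  under-resolve it.

## Pattern taxonomy

`classifyMask()` reduces a binary mask to connected components (EBImage,
8-connectivity) and applies a fixed decision cascade — coverage $\ge 0.9$ is
uniform; $\ge 20$ components with median equivalent diameter under 3 mm
(fine) or 8 mm are dots; among components $\ge 5$ mm, a majority of rings
(hole-filling grows the area $\ge 20\%$) is annular, split large/small at a
20 mm median outer diameter; arc fragments (solidity $< 0.5$, no hole)
outnumbering closed rings is broken annular; a majority of filled discs
(solidity $\ge 0.9$) is circular.  The thresholds live in `patternRules()`
and are a reproducible surrogate for what is, in the clinic, a visual
judgement; the large/small annular boundary in particular has no canonical
value.  `sweepRegimes()` maps $P_{min}$ and the reference-stimulus class
over parameter grids, resumably.

## Intradermal injection analytics

A bolus injection is modelled as pure diffusion from a point source,
$u(r,t) = \frac{u_0}{4\pi D t} e^{-r^2/4Dt}$, with the wheal visible where
$u \ge u_r$.  The visible radius
$r^*(t) = \sqrt{4Dt \log(u_0/(4\pi D u_r t))}$ (plus the initial wheal size
$r_0$) rises to a maximum at $t^* = u_0/(4\pi D u_r e)$ and the expansion
velocity `expansionVelocity()` decreases monotonically to zero there —
the injection wheal is fastest immediately and stops by itself.

`estimateDiffusion()` implements the multi-dose estimation workflow: fit
each dose's radius series with the saturating exponential
$Y_0 + (P - Y_0)(1 - e^{-\alpha t})$, extract the stop time as the first
time the fitted derivative drops to $\epsilon = 0.005$ mm/min (the imaging
pixel resolution) and the radius there, then equate the point-source
solution between dose pairs — the threshold $u_r$ is dose-independent — and
solve each pair for $D$ by a log-spaced scan plus bisection on
$[10^{-4}, 10]$ mm²/min, averaging the three pairwise estimates.  Doses
enter as $u_0 = u_{nd}\times\text{dose}$ with $u_{nd} = 0.03$ ml/µg.  Two
numerical properties matter:

* The pair equations are solved with each dose's own $(t^*_i, r_i)$ and the
  diffusion radius $r_i = r^*_{max,i} - Y_{0,i}$, because the initial wheal
  size is not part of the diffusion footprint.  A shared-radius variant
  (the pair mean in both exponentials) is available via `shared_r = TRUE`.
* At the exact maximum of the radius curve the pair equality degenerates to
  $t^*_i/t^*_j = u_{0,i}/u_{0,j}$, independent of $D$ — so the estimate is
  intrinsically ill-conditioned from plateau data alone.  The
  $\epsilon$-criterion stops slightly *before* the maximum, which is what
  keeps the root well-defined; it also means the estimate's dispersion under
  observation noise is considerable even when its median is accurate.

`makeDoseFixtures()` generates synthetic dose series in place of clinical
measurements: radii follow the analytic curve during expansion and then hold
their maximum (the wheal persists; skin does not recover within the
observation window — the same asymmetry the hysteretic $H$ encodes), sampled
on per-dose windows reaching 2.5 stop times so the plateau is inside the
data for every dose, with seeded Gaussian noise.  Under this generator the
full loop — fixtures, fits, extraction, pairwise estimation — returns the
generating $D$ within about 2.5% noise-free and within 4% in the median over
50 seeds at 0.1 mm noise.  What the fixtures do *not* emulate: between-
subject variability, the asymmetric and skewed area measurements of real
photographs, and any departure of real histamine transport from ideal
point-source diffusion; passing these tests validates the estimation
machinery, not the biological model.

## Front speed: simulation versus observation

Measured with a central supra-threshold stimulus in the radial solver, the
ignited wheal front travels at a dimensionless speed of about
$7\times10^{-3}$ — converged from 64 to 4096 grid points, independent of the
stimulus amplitude above the ignition threshold, and consistent with the
analytic bound above.  With the default scales that is roughly 28 mm/hr.

This is the package's most important caveat: clinically, wheals in chronic
spontaneous urticaria expand about two orders of magnitude more slowly
(≈ 0.25 mm/hr).  Within this model and its representative parameters we
found no convergent discretization, threshold level, or stimulus protocol
that produces such a slow front: sub-threshold stimuli collapse without
expanding at all, supra-threshold ones ignite the fast front, and the sharp
ignition boundary leaves no intermediate creeping regime.  Store depletion
terminates the front (each cell's spike exhausts its store shortly after the
front passes) but does not slow it.  The slow clinical expansion therefore
appears to require physics outside this equation — or a much smaller
effective diffusivity than the injection-derived value.  The package reports
what the equations yield; `scripts/acceptance.R` recomputes both the
simulated speed and its ratio to the injection-model speed so the
discrepancy is visible rather than hidden.

## Worked example

```{r, eval = FALSE}
p <- kineticParams()
cfg <- solverConfig(grid_n = 1024, t_end = 60, dt = 2e-3,
                    snapshot_interval = 2, radial_mode = TRUE)
traj <- rdRun(p, stimulusSpec(r = 0.6, seed = 1), whealParams(), cfg)
tr <- trackFront(traj)
speedToDimensional(tr$speed, scaleSet())   # front speed in mm/hr

fx <- makeDoseFixtures(noise_sd = 0.1, seed = 1)
estimateDiffusion(fx)                      # recovers D ~ 0.085 mm^2/min
```

## Known limitations

* The model is conceptual: histamine stands in for the whole mediator
  cocktail, the inhibitor is unidentified, and histamine resynthesis is
  ignored, so every cell can wheal at most once per episode.
* Basal release drains the store even without a stimulus, which bounds the
  duration of any episode at $U_{tot}/(\gamma u_0^*)$ time units (about 11.6
  hours at the defaults) — arguably a feature, but also a strong assumption.
* $P_{min}$ values depend on the grid through the per-cell random stimulus;
  compare them only at a fixed resolution and seed.
* The front-speed discrepancy described above.
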