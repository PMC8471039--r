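---
title: "Guiding a microswimmer with wall-generated flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guiding a microswimmer with wall-generated flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallswim)
```

## The model

A spherical swimmer self-propels at constant speed $v$ in the $(x,z)$ plane
above an active wall at $z = 0$.  The wall (think of a carpet of magnetically
actuated artificial cilia) carries a metachronal travelling wave whose
amplitude $u(t)$ we control.  In the far field the wave induces the flow

$$U_x = u\,e^{-kz}(1-kz)\sin(kx-\omega t),\qquad
  U_z = -u\,e^{-kz}\,kz\cos(kx-\omega t),\qquad
  \Omega_y = \tfrac12 u\,e^{-kz}\,k\sin(kx-\omega t),$$

an incompressible field organised into counter-rotating cells of width
$\pi/k$ whose horizontal component reverses across the height $z = 1/k$.
The swimmer's heading is the angle $\theta$ from the $+z$ axis, so its free
velocity is $(-v\sin\theta,\, v\cos\theta)$ and $\theta = -\pi/2$ points
along $+x$; $\theta$ is kept unwrapped so net rotation is measurable.  The
controlled state $X = (x, z, \theta)$ obeys

$$\dot x = -v\sin\theta + U_x,\qquad
  \dot z = v\cos\theta + U_z,\qquad
  \dot\theta = \Omega_y,$$

optionally augmented by the far-field interaction of a squirmer (stresslet
parameter $B_2$, radius $a$) with the no-slip wall,

$$U_x^b = -\frac{3a^2B_2}{40z^2}\sin 2\theta,\qquad
  U_z^b = \frac{9a^2B_2}{16z^2}\cos 2\theta,\qquad
  \Omega_y^b = -\frac{3a^2B_2}{40z^3}\sin 2\theta .$$

Everything is nondimensionalised with $k = v = 1$ by default, so $\omega$,
times and speeds are the ratios $\omega/kv$, $tkv$ and $u/v$; dimensional
parameters are accepted everywhere.

Two modelling choices deserve mention.  First, the trigonometric form of the
interaction term is implemented with double angles; this is what makes a
puller ($B_2>0$) heading along the wall ($\cos 2\theta = -1$) attracted to it
and a pusher repelled, the behaviour the interaction is meant to encode (a
squared-angle reading, which would produce no vertical effect at
$\theta=-\pi/2$, is available via `squirmer_reading = "squared"` for
comparison).  Second, "crashing" is flagged when $z$ falls to the swimmer
radius $a$ when the interaction is enabled, and to $0.05/k$ in point-swimmer
mode; no near-field or contact mechanics is modelled.

## Local controllability around free trajectories

With zero reference control the swimmer travels on the straight line
$X_{\rm ref}(t) = (x_0 - vt\sin\theta_0,\ z_0 + vt\cos\theta_0,\ \theta_0)$.
Linearising about it gives a time-varying system
$\dot X = A(t)X + B(t)u$ whose controllability follows from the Kalman-type
condition: invertibility, at some time, of $[B \mid B_1 \mid B_2]$ with
$B_1 = \dot B - AB$, $B_2 = \dot B_1 - A B_1$.  Along the reference every
column has the form $e^{-kz(t)}\,(P(t)\sin\varphi + Q(t)\cos\varphi)$ with
polynomial coefficients, which `kalman_blocks()` exploits to build the blocks
exactly.  The determinant has the closed form

$$\Delta(t) = \tfrac12 e^{-3kz(t)}\,k^3 v\,\omega_c \cos\theta_0
  \left[\omega_c\, z(t)\cos\varphi(t) + v\cos\theta_0 \sin\varphi(t)\right],$$

with the comoving frequency $\omega_c = \omega + kv\sin\theta_0$ (the wave
frequency seen from the translating swimmer) and
$\varphi(t) = kx_0 - \omega_c t$.  It was derived symbolically and is
verified in the tests against a finite-difference construction of the blocks
to $10^{-5}$ relative accuracy on dozens of random instances.

$\Delta$ vanishes identically in exactly four situations, classified by
`classify_degeneracies()`:

* $k = 0$ — a uniformly sliding wall cannot rotate the swimmer (trivially
  uncontrollable);
* $v = 0$ — a passive particle only follows one flow line (trivially
  uncontrollable);
* $\omega_c = 0$ — the swimmer translates with the wave front and sees a
  frozen flow;
* $\cos\theta_0 = 0$ — **wall-parallel** initial heading: the reference
  height is constant, so the horizontal and angular flow responses are
  proportional ($\Omega_y / U_x = k/(2(1-kz_0))$ pointwise) and the
  linearisation cannot separate them.

The last case deserves emphasis because wall-parallel transport is the main
use case: its lack of first-order controllability is a statement about
arbitrarily small controls around the straight line, not about the
steerability of the nonlinear system, which regains independent authority
through height excursions.  It also foreshadows a genuine physical coupling:
at fixed height, any control history that pushes the swimmer forward rotates
it toward the wall by a proportional amount.  Otherwise the zeros of
$\Delta$ are isolated and the system is locally controllable.

## Closed-form transport estimates

For wall-parallel transport the natural strategy is to flip the wave
amplitude every time the swimmer crosses a flow-cell border, keeping the
horizontal push always favourable.  Holding $z$ and $\theta$ frozen, the
characteristic flow speed at height $z_0$ is
$V_0 = u_{\max}e^{-kz_0}(1-kz_0)$, maximal in magnitude
($u_{\max}e^{-2}$) at $z_0 = 2/k$.  `constant_control_x()` gives the exact
frozen-state solution between switches: in the phase $y = kx - \omega t$ the
dynamics are autonomous with comoving frequency
$\omega_c = \omega + kv\sin\theta_0$ and

$$x(t) = \frac1k\left[\omega t + 2\arctan\!\left(
  \frac{kV_0 - \omega_0\tan(\omega_0(t-T_0)/2)}{\omega_c}\right)\right],
  \qquad \omega_0 = \sqrt{\omega_c^2 - k^2V_0^2},$$

with the arctan–tan composition unwrapped across half-periods (the phase
reference $T_0$ is an explicit argument).  The leading-order displacement
contributed by the flow per cell crossing is $\Delta x = 2V_0/\omega$, the
average flow gain solves the self-consistency relation
$v_{\rm flow} = \Delta x / T_{\rm switch}$, giving at lowest order

$$v_{\rm flow} = \frac{2V_0}{\pi}\Big[1 - \frac{k}{\omega}\Big(v\sin\theta_0
   + \frac{2V_0}{\pi}\Big)\Big],\qquad
  T_{\rm switch} = \frac{\pi}{\omega - k(v_h + v_{\rm flow})},$$

where $v_h = -v\sin\theta_0$ is the free horizontal speed (for a swimmer
heading along $+x$, $v_h = v$; the magnitude $|V_0|$ is used, the transport
direction being set by the heading).  The sign conventions here were fixed
once against a frozen-state simulation oracle of the synchronised strategy,
which reproduces the implemented $T_{\rm switch}$ to within 2% and
$v_{\rm flow}$ to within the first-order error (about 11% at
$V_0/\omega \approx 0.17$).  The estimated minimal transit time and the
leading-order boost at the optimal height follow as

$$T_{\min} = \frac{x_1-x_0}{v+v_{\rm flow}},\qquad
  b = \frac{v_{\rm flow}}{v} = \frac{2e^{-2}}{\pi}\frac{u_{\max}}{v},$$

about 8.6% at $u_{\max} = v$ and 43% at $u_{\max} = 5v$.

## Minimum-time steering

Three steering objectives are treated by `solve_time_optimal()`:
wall-parallel displacement (reach $x_1$ with the height restored),
reorientation (reach $\theta_1$ with the height restored), and wall-distance
change (reach $z_1$).  The maximum principle for the control-affine dynamics
gives a bang–bang optimum: with Hamiltonian $H = p\cdot f + p_0$ the control
switches at the zeros of the switching function

$$h(p, X) = e^{-kz}\Big[\big(p_x(1-kz) + \tfrac{k}{2}p_\theta\big)
  \sin(kx-\omega t) - p_z\,kz\cos(kx-\omega t)\Big],$$

taking the values $u_{\min}$, $u_{\max}$ (the singular value 0 only on a
measure-zero set).  The costates obey $\dot p = -(\partial f/\partial X)^T p$,
the sign convention under which the bang–bang law maximises $H$.

Because the optimum is exactly bang–bang, the solver parametrises the control
by its structure — an initial sign and the durations of the alternating
segments — rather than by values on a dense grid.  The free final time is
the first-crossing time of the target surface (located to machine precision
inside a compiled fixed-step RK4 rollout) for the displacement and
wall-distance problems, and the sum of durations for reorientation.  The
remaining terminal equalities are enforced by an augmented-Lagrangian outer
loop around box-constrained quasi-Newton over the durations, followed by a
damped Newton correction on the trailing durations that drives the residuals
to the $10^{-6}$ terminal tolerance; a quadratic path penalty keeps the
trajectory above a floor set at 1.2 times the crash threshold, so converged
solutions graze the floor from above without crashing.  Optimisation rollouts
use step $h = 0.004$ (nondimensional time) and reported trajectories
$h = 0.0015$; both resolve the fastest phase rate of the study scenarios by
two orders of magnitude.

The solver refines a deterministic family of seeds and returns the best
feasible local solution:

* *cell-synchronised* seeds — switch times harvested from simulating the
  synchronised switching policy at the launch height, with and without a
  phase-offset height regulation;
* *uniform cadence* seeds at the analytic switch period, with phase
  variants;
* *dive–surf–climb* seeds for displacement — descend to a prescribed height,
  surf the (much stronger) near-wall flow, climb back near the target;
* *approach–rotate–escape* and staged-rotation seeds for reorientation,
  which alternate capped rotation stints with re-descents when the rotation
  itself lifts the swimmer.

Two distinct local regimes emerge for the displacement problem, and both are
genuine solutions of the stated problem.  Near-launch-height solutions
follow the synchronised cadence closely but pay the cost anticipated by the
controllability analysis: forward push and wallward rotation are rigidly
coupled at fixed height, so the heading drifts and the realised gain
(about 24–31% at the strong operating point) falls short of the frozen-state
estimates.  Wall-skimming solutions dive towards the crash floor where the
available flow is several times stronger, and achieve materially shorter
times (41.5% effective-speed gain at the strong operating point); their
switch cadence is heterogeneous and no longer described by the frozen-state
period.  The closed-form $T_{\min}$ estimate happens to describe the best
(diving) solutions to within 10% across the study grid
($\omega \in \{4,8,12\}$, $|V_0| \in \{0.62, 0.34\}$), while the cadence
estimate describes the synchronised-regime solutions, whose typical
inter-switch interval (the median after discarding the short double-switch
height corrections) matches it to within 10%.  The tests assert exactly
these two statements.  The frozen-state estimates are optimistic about the
absolute gain — they neglect the heading drift entirely — which is why the
measured headline improvement at the strongest operating point is about
41.5% rather than the ~50% the estimate suggests.

For verification rather than solution, `pmp_switching_consistency()` checks
a converged displacement arc against the maximum principle: costate
solutions are linear in their terminal value, so two backward basis
integrations (with $p_\theta(T) = 0$, the transversality condition for a
free final heading) span all admissible costates, and a grid scan over the
terminal direction finds one whose switching-function sign pattern matches
at least 90% of the applied control samples.

## Driving policies

Two implementable policies mimic the optimal switching structure.  The open
loop $u(t) = u_{\max}\,\mathrm{sgn}\sin(\pi t/T_{\rm switch} + \phi)$ needs
no measurement but must be synchronised in advance; the feedback law
$u(t,X) = -u_{\max}\,\mathrm{sgn}\sin(kx - \omega t)$ switches on the
measured cell border crossings.  `run_policy_experiment()` integrates either
with event-accurate switching (the switching surfaces are located by root
finding and the integrator restarts there) and reports transport metrics;
`compare_policies()` sweeps a relative error on the open-loop period.

Measured on the common launch state $(0, 3, -\pi/2)$ over $T = 5$ with
$u_{\max} = 5$, $\omega = 4$: the feedback run gains about 30% in mean
horizontal speed — close to the flow-gain estimate at the launch height over
the first periods, before the wallward heading drift erodes it — while
slowly rotating toward the wall; the open loop matches the feedback gain
when its period is exact and degrades steeply with period error (−5% error
already removes the gain; −10% crashes the swimmer), which is the practical
argument for feedback.  With the squirmer-wall interaction enabled the
minimum wall distance over the run is ordered monotonically in $B_2$
($-100 < -20 < 0 < +20$ gives decreasing clearance), pushers being repelled
from and pullers attracted to the wall; the $B_2 = +20$ puller converges to
the wall fastest and loses most of its gain.

## Scenario presets and what they do (not) represent

`scenario_preset()` / `make_figure_fixtures()` provide the named study
scenarios: six displacement problems ($|V_0| \in \{0.62, 0.34\}$ realised by
back-solving the launch height from the characteristic speed at
$u_{\max}=5$, times $\omega \in \{4,8,12\}$, course $x: 0 \to 2\pi$), three
reorientation problems ($(\theta_0,\theta_1)$ = $(-\pi/4,-3\pi/4)$,
$(-\pi,0)$, $(-\pi/2,\pi/2)$), and five policy runs from $(0,3,-\pi/2)$
($T=5$, $u_{\max}=5$; open loop, feedback, and feedback with
$B_2 \in \{-20,-100,+20\}$).  Where the scenario definition leaves a value
open, the presets choose once: the farther of the two heights realising a
given $|V_0|$ (safer from the wall); launch height $2/k$ for the
reorientation problems (the optimal transport distance); squirmer radius
$a = 0.3/k$ (small against the wavelength, keeping the $|B_2| = 20$ effects
modest as intended); $\omega = 4$ for the policy runs.

These scenarios are synthetic study conditions, not data: they exercise the
model under its own assumptions.  Passing tests therefore demonstrate the
internal consistency of model, estimates, optimal control and policies — not
the fidelity of the far-field flow or the squirmer interaction to a real
cilia carpet.  In particular the far-field expressions are extrapolated when
trajectories skim the crash floor, the model is strictly planar, and the
feedback policy assumes the horizontal position is measured exactly.

## Numerical choices and limitations

* Adaptive integration (`integrate_swimmer`) uses `deSolve::lsodar` with
  `rtol = 1e-8`, `atol = 1e-10`; bang–bang policies are integrated
  segment-wise between switching-surface roots, so discontinuities never
  cross a solver step.  Function-valued controls with internal
  discontinuities are integrated as given and may degrade the step
  controller — the policy interface is preferred for bang–bang laws.
* The compiled solver kernel clamps $e^{-kz}$ arguments and, during
  exploratory rollouts, continues smoothly slightly past the wall; physical
  validity is restored by the path floor and the crash flag.
* Terminal equalities: $10^{-6}$ (nondimensional), usually met to $10^{-8}$
  or better after the Newton pass.  Reorientation horizons are capped at
  $20 z_0/v$, a solver box rather than a modelling statement.
* The reorientation solutions reproduce the approach–rotate–escape
  structure, but "little heading change on approach" is relative: up to half
  of a small total rotation can accumulate on the way down when the target
  rotation is small.
* The solver is a local method on a deterministic multi-start; it can in
  principle miss better remote optima, and the two-regime structure above
  shows the landscape does contain well-separated basins.
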