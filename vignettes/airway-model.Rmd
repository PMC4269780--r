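---
title: "A multiscale model of dynamic bronchoconstriction in intact airways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of dynamic bronchoconstriction in intact airways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymech)
```

## The scientific problem

Deep inspirations and tidal breathing dilate constricted airways in healthy
subjects, and length fluctuations applied to isolated airway smooth muscle
(ASM) strips sharply reduce mean contractile force — yet transmural-pressure
oscillations applied to isolated *intact* airways produce only modest
bronchodilation. `airwaymech` implements a biomechanical model of the intact
airway built to probe this paradox: actomyosin cross-bridge kinetics at the
subcellular scale are embedded, as contractile hoop fibers, in a nonlinear
strain-stiffening elastic wall, and the two scales are coupled in both
directions. The central mechanical idea is competition between passive
strain-stiffening of the extracellular matrix (collagen recruitment) and
active ASM force generation, which together make the *effective airway
stiffness* — the reciprocal slope of the static pressure–radius relation —
a strongly non-monotonic function of transmural pressure that is reshaped
by contractile agonist.

## Tissue scale: the airway wall

The airway is an axisymmetric thick-walled cylinder of fixed length in
plane strain (no axial displacement). The wall occupies undeformed radii
$R_a \le R \le R_b = R_a + \chi$ and is incompressible, so a deformed lumen
radius $r_a$ determines the whole deformation map:

$$ r(R) = \sqrt{r_a^2 + R^2 - R_a^2}, \qquad
   \lambda_\theta = r/R, \quad \lambda_r = 1/\lambda_\theta .$$

The Cauchy stress is a neo-Hookean matrix (shear modulus $\mu$) plus a
hoop-directed fiber family carrying both the passive collagen response and
the active ASM stress. The fiber energy is exponential,

$$ \Phi(\lambda) = \frac{C_1}{2 C_2}\left[e^{C_2\, e(\lambda)^2} - 1\right],
 \qquad e(\lambda) = \begin{cases}
   \max(\lambda^2 - \lambda_s^2,\, 0) & \lambda \ge 1 \\
   \lambda^2 - 1 & \lambda < 1,
 \end{cases} $$

where $C_1$ scales fiber density/stiffness, $C_2$ the nonlinear stiffening,
and $\lambda_s$ is a recruitment (slack) stretch: wavy collagen carries
tensile load only beyond $\lambda_s$, which produces the compliant toe
region of the passive pressure–radius curve and places the passive
stiffness minimum at a small positive transmural pressure rather than at
zero. In compression the fiber network engages immediately but *buckles*
beyond a modest compression: for fiber stretch below $\lambda_b$ (default
0.94) the compressive strain measure plateaus at $\lambda_b^2 - 1$, so
strongly constricted states are held by the matrix rather than an
ever-stiffening fiber bed. Without the plateau, contracted airways are
nearly rigid and transmit almost no tidal strain to the contractile
machinery — contrary to the measurable strain amplitudes of constricted
intact airways. The active stress enters the hoop Cauchy stress as
$A_\mathrm{eff}\,\lambda_\theta$ (deformed-area convention).

Equilibrium integrates the radial momentum balance
$\mathrm{d}\tau_{rr}/\mathrm{d}r = (\tau_{\theta\theta}-\tau_{rr})/r$
across the wall between the boundary stresses, with the sign convention
$P_\mathrm{TM} = \tau_a - \tau_p$ (lumen minus external pressure;
$\tau_p = 0$ in all replicated protocols). The integral is evaluated by
64-node Gauss–Legendre quadrature in the undeformed coordinate and the
lumen radius located by a bracketed scalar root solve polished below
$10^{-9}\mu$. A compressible linear-elastic parenchymal annulus (Young's
modulus one tenth of the matrix modulus, $\nu = 0.3$) is available behind a
flag via the classical Lamé solution, but is disabled by default to mirror
experiments on airways dissected free of parenchyma.

## Cell scale: Huxley–Hai–Murphy cross-bridge kinetics

Myosin heads occupy four states — unattached/unphosphorylated $M$,
unattached/phosphorylated $M_p$ (via MLCK at rate $k_1$, the agonist
surrogate), attached cycling cross-bridges $AM_p$, and dephosphorylated,
slowly detaching latch bridges $AM$ — resolved over the bond extension $x$
(in powerstroke units $h$). Attachment and detachment are strain dependent:
$f_p = f_{p1} x/h$ on $0 \le x \le h$ and zero outside; $g_p$ and $g$ grow
linearly in $x$ for $x \ge 0$ (coefficients $g_{p1}$ and the latch
coefficient $g_1$) and take constant fast values for compressed bridges
($x < 0$). Cycling bridges dragged beyond the powerstroke ($x > h$)
release rapidly, with slope $f_{p1} + g_{p1}$ — the yield branch through
which imposed stretch prunes actively cycling cross-bridges and lowers
mean force; latch bridges keep their slow slope $g_1$ everywhere on
$x \ge 0$, which is why latch-dominated contracted states resist pressure
fluctuations. Because no bridges are attached beyond $h$ at zero sliding
velocity, the yield branch leaves every isometric (static) prediction
unchanged. Filament sliding at velocity $c$ transports all four
populations:

$$ \frac{\partial n}{\partial t} - c\,\frac{\partial n}{\partial x}
   = \text{reactions}(n; x). $$

The transport is discretised with first-order upwind differences on a
241-point grid spanning $[-2h, 3h]$, sub-stepped so that the Courant number
never exceeds one and the fastest reaction loses at most a quarter of a
state per sub-step (at integer Courant number pure advection is exact).
Populations advected off the grid are absorbed as detached, so
$n_M + n_{M_p} + n_{AM_p} + n_{AM} = 1$ holds pointwise to round-off. The
isometric steady state is available in closed form per grid point; where
the balance is singular (exactly $x = 0$) the attached pool is conserved
and the detached pool split by the $k_1/k_2$ equilibrium.

The contractile-unit force is the first moment of the attached populations,
$F = \kappa \int x\,(n_{AM_p} + n_{AM})\,\mathrm{d}x$, and the tissue-scale
isometric active stress is $A = \beta F$ with $\beta = 100$ counting
filaments per unit area. $\kappa$ is the single stress-scale constant of
the model (see calibration below).

## Coupling the scales

The mid-wall fiber is the representative contractile element: its stretch
rate sets the sliding velocity, $c = -(L_{cu}/2)\,\dot\lambda_f$, with
$L_{cu}$ the contractile-unit length in powerstroke units (tissue
shortening transports bridges toward smaller extension), and its stretch
sets the force–length state of the machinery. The latter is a
filament-overlap factor applied to the isometric active stress,

$$ A_\mathrm{eff} = A \cdot \mathrm{FL}(\lambda_f^{mid}), $$

with $\mathrm{FL} = 1$ below `fl_on`, a smoothstep taper to zero at
`fl_off`, and zero beyond: contractile units stretched far past their
optimum lose actin–myosin overlap and generate no force, so strongly
inflated airways cannot sustain active stress and the activated static
curves merge with the passive one at high pressure. No penalty applies on
the shortening side, where the latch-dominated contracted states live.
This stretch dependence is what the static-curve computation iterates
self-consistently; it is evaluated at the mid-wall fiber (rather than per
radial shell) because the same fiber drives the velocity coupling and the
reported contractile force.

Each time step of the coupled model (default $\Delta t = 10$ ms) is an
operator split: evaluate the pressure waveform
$P_\mathrm{TM}(t) = P_0 + \Delta P \sin(2\pi t/t_0)$; advect/react the
populations with the current $c$; recompute $A$; re-solve the quasistatic
wall equilibrium; update $c$ from the mid-wall stretch change. Because the
wall is elastic and inertialess, an explicit split can jump between
equilibrium branches in a single step when a fold of the pressure–radius
relation is crossed, which would drag the bridge distribution unphysically
far in one step. The stepper therefore monitors the implied velocity
change and, above a threshold (1 $x$-unit/s), re-solves the step
implicitly: the new radius is the root of the wall balance evaluated with
the active stress produced by populations advected at the very sliding
velocity implied by that radius change. This restores the force–velocity
limit on contraction and yield speed. Warm starts for the equilibrium
solve march directionally from the previous radius — in the direction of
the net force imbalance — so folded relations resolve onto the stable
branch the dynamics actually reach.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| $R_a$, $\chi$ | undeformed lumen radius, wall thickness | 1, 0.3 (0.45 remodeled) | $R_a$ |
| $\mu$ | matrix shear modulus | 22 | cmH₂O |
| $C_1$, $C_2$ | fiber stiffness scale, stiffening exponent | 2, 8 | cmH₂O, — |
| $\lambda_s$ | collagen recruitment stretch | 1.08 | — |
| $\lambda_b$ | compressed-fiber buckling stretch | 0.94 | — |
| `fl_on`, `fl_off` | overlap taper window (mid-wall stretch) | 1.25, 1.30 | — |
| $k_1$ | MLCK rate (agonist surrogate) | 0.005–0.05 in protocols | s⁻¹ |
| $k_2$ | MLCP rate | 0.04 | s⁻¹ |
| $f_{p1}$, $g_{p1}$, $g_{p,-}$ | attachment / cycling detachment | 0.88, 0.22, 4.4 | s⁻¹ |
| $g_1$, $g_-$ | latch detachment slope, compressed-latch rate | 0.1 (0.01 variant), $20 g_1$ | s⁻¹ |
| $\beta$ | filaments per unit area | 100 | — |
| $\kappa$ | cross-bridge stiffness (stress scale) | 1.8 | cmH₂O per $\kappa h^2$ unit |
| $L_{cu}$ | contractile-unit length | 150 | $h$ |
| $P_0$, $\Delta P$, $t_0$ | waveform mean, amplitude, period | 7.5, 2.5, 5 | cmH₂O, cmH₂O, s |

The kinetic constants other than $k_1$ and $g_1$ follow the standard HHM
parameterisation for airway smooth muscle; all are overridable through
`rate_parameters()`. Four constants are not observable separately and were
calibrated once, jointly, against the qualitative and quantitative features
the model is meant to reproduce — the passive pressure–radius curve of an
intact bovine airway and its stiffness minimum at low positive pressure,
the rightward shift of the activated curves with the activation-ordering
band of the stiffness curves, and the behaviour of the protocols under
tidal oscillation: the stress scale $\kappa$, the MLCP rate $k_2$ (which
sets how isometric force saturates across the protocol's $k_1$ range),
the overlap window (`fl_on`, `fl_off`), and $L_{cu}$. They are fixed
package defaults, not tuning dials; the acceptance script re-derives the
corresponding model predictions from scratch at every run.

## Protocols and metrics

`protocol1_spec()` applies increasing agonist ($k_1$ = 0.005, 0.025,
0.05 s⁻¹; nominally 12 min each) at fixed mean pressure 7.5 cmH₂O, either
statically or with 2.5 cmH₂O tidal oscillations. `protocol2_spec()`
contracts the airway at $k_1$ = 0.025 s⁻¹ and mean pressure 5 cmH₂O
(nominally 15 min), then applies oscillations of amplitude 1.25, 2.5 and
5 cmH₂O. Stages integrate until the end-of-cycle radius changes by less
than a relative tolerance ($10^{-5}$ by default) between successive
periods, so desk-scale runs can cut the nominal durations once the
oscillatory state is stable. Reported metrics mirror the experimental
panels: end-of-final-oscillation radius and wall thickness (sampled when
$P_\mathrm{TM} = P_0$) in percent of the prestressed baseline, the strain
amplitude $\Delta r = (r_a^{max} - r_a^{min})/(2 R_a)$ of the final cycle,
and pressure–radius loop statistics (mean radius, shoelace area, dynamic
compliance). The baseline and contracted states of Protocol 2 get their
strain amplitudes from two-cycle probe oscillations of amplitude
1.25 cmH₂O, which are diagnostic only — the protocol continues from the
unprobed state. Remodeling (`apply_remodeling()`) thickens the wall
radially outward at constant fiber density, so total contractile and
collagen content rise with wall volume.

## Fitting and synthetic data

`fit_passive_materials()` recovers $(\mu, C_1, C_2)$ from passive
pressure–radius records by Levenberg–Marquardt least squares on the radius
residuals (uniform weights — radius is the measured quantity), with a
deterministic $3{\times}3{\times}3$ log-spaced multi-start grid screened by
residual norm; $\mu$ and $C_1$ are optimised on the log scale and $C_2$ is
bounded below by zero so a non-stiffening truth is recoverable at the
boundary. `fit_logistic()` and `stiffness_from_fit()` implement the
logistic smoothing of experimental-style curves with the analytic
reciprocal-derivative stiffness, whose minimum sits at the logistic
midpoint by construction.

`generate_pr_dataset()` evaluates the model's static curve and adds
multiplicative Gaussian radius noise (default 2%, seeded), emulating
quasistatic measurements on isolated intact airways. It reproduces the
sampling structure of such data but none of the apparatus effects (servo
dynamics, tubing compliance, adventitial damage), and its noise is
independent across pressures — so passing recovery tests demonstrate
identifiability under the model's own assumptions, not robustness to
correlated experimental artefacts.

## Numerical choices and problem sizes

Defaults throughout: 241-point bond-extension grid on $[-2h, 3h]$; 64-node
Gauss–Legendre wall quadrature; $\Delta t = 10$ ms with automatic kinetic
sub-stepping; equilibrium residual below $10^{-9}\mu$; stability tolerance
$10^{-5}$ relative per cycle. The test suite integrates minutes-scale
protocol segments and 20-seed fitting ensembles; the acceptance script
runs the static characterisation on a 0.25 cmH₂O pressure grid and
Protocol 1 through its first two stages with stability-criterion
durations. These sizes were chosen so the whole analysis reruns
comfortably on a laptop while leaving the reported quantities insensitive
to further refinement (halving the time step moves end-of-cycle radii by
under $10^{-3}$ relative).

## Dynamic regimes and a known bifurcation

Under tidal pressure oscillation the coupled model has two robust
attractors at moderate-to-high agonist: a contracted, latch-dominated
state that admits only small radius excursions, and an uncontracted state
in which oscillatory yield prunes the cycling bridges as fast as MLCK can
recruit them. Which one is reached depends on the competition between
force build-up and strain-driven pruning, and hence on $L_{cu}$: sweeping
it shows the oscillatory-minus-static end radius of the moderate-agonist
stage growing smoothly to roughly $+2$–$3$ percentage points of baseline
and then jumping discontinuously to $\sim{+}35$ as the oscillation begins
to prevent contraction outright. Intermediate levels of sustained
bronchodilation are not stable states of this implementation: under
pressure (force) control the cross-bridge displacement amplitude is
bounded by the mean bond extension times the *relative* force
fluctuation, which caps mean-force depression in the contracted state at
a few percent. $L_{cu} = 150$ sits on the contracted side of the
bifurcation with a comfortable margin, so the package reproduces the
qualitative experimental picture — limited tidal bronchodilation, dose
response, growing hysteresis with amplitude, and full reversal at the
largest Protocol-2 amplitude — while the quantitative oscillatory-static
gap at moderate agonist remains smaller than the most optimistic model
prediction in the literature.

## Known limitations

The model is axisymmetric: it cannot buckle, fold, or develop the mucosal
rosettes of strongly constricted real airways, and its compression response
at negative transmural pressure stands in for those mechanisms. The tissue
is elastic — all hysteresis in pressure–radius loops is of cross-bridge
origin, with no passive viscoelasticity. Calcium signalling upstream of
$k_1$, strain-dependent modulation of $g_1$, axial extension, helical fiber
kinematics beyond a projection factor, and inward (epithelial) remodeling
are out of scope. The quasistatic wall approximation neglects airway
inertia and any fluid–structure interaction with airflow.
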