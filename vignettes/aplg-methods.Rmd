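---
title: "Hydrodynamics of the active-passive lattice gas: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamics of the active-passive lattice gas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aplg)
```

## The model

The active-passive lattice gas (APLG) is an exclusion process on a periodic
two-dimensional square lattice of spacing $h$ mixing three species: active
particles oriented right ($\sigma = +1$) or left ($\sigma = -1$) and passive
particles ($\sigma = 0$), at most one particle per site. Passive particles
hop to each neighbor at rate $D_T/h^2$; active particles hop at
$D_T/h^2 + \sigma v_0/(2h)$ rightward, $D_T/h^2 - \sigma v_0/(2h)$ leftward
and $D_T/h^2$ vertically, and flip orientation at rate $D_R$. Jumps into
occupied sites are aborted. After rescaling time by $D_R^{-1}$ and space by
$\sqrt{D_T/D_R}$, the control parameters are the Péclet number
$\mathrm{Pe} = v_0/\sqrt{D_T D_R}$, the domain length $L$, and the active
and passive volume fractions $\phi_a$, $\phi_p$.

In the hydrodynamic limit $h \to 0$ the species densities
$\rho_\sigma(x, t)$ obey, in one space dimension (self-propulsion is purely
horizontal, so vertical structure relaxes diffusively and the macroscopic
dynamics is $x$-only),
$$
\partial_t \rho_\sigma =
  \partial_x\!\left[d_s(\rho)\,\partial_x \rho_\sigma
  + \rho_\sigma \mathcal{D}(\rho)\,\partial_x \rho\right]
  - \mathrm{Pe}\,\partial_x\!\left[\rho_\sigma s(\rho)\, m
  + \sigma d_s(\rho)\rho_\sigma\right] - \sigma m ,
$$
with $\rho = \rho_+ + \rho_- + \rho_0$, magnetization $m = \rho_+ - \rho_-$,
$\mathcal{D}(\rho) = [1 - d_s(\rho)]/\rho$ and $s = \mathcal{D} - 1$. Here
$d_s(\rho)$ is the tagged-particle self-diffusion coefficient of the
symmetric exclusion process. It has no closed form; the package defaults to
the cubic polynomial approximation
$d_s(\rho) = (1-\rho)\bigl(1 - \alpha\rho + \tfrac{\alpha(2\alpha-1)}{2\alpha+1}\rho^2\bigr)$
with $\alpha = \pi/2 - 1$, which is exact in value and first derivative at
$\rho = 0, 1$. The coefficient interface is pluggable: any polynomial
$d_s$ with $d_s(0) = 1$ may be supplied, and $\mathcal{D}$ is obtained by
exact polynomial division so that the $\rho \to 0$ limit never divides by
zero. The identity $\rho\mathcal{D} + d_s = 1$ holds exactly and is used
repeatedly (for example, the collective diffusivity of the total density is
exactly one).

## Stochastic simulation

`gillespie_run()` simulates the lattice model exactly. Because blocked jumps
are retained as null events, the total per-particle rate is configuration
independent ($4/h^2$ for passive, $4/h^2 + 1$ for active particles), so
event selection is O(1) per event and the chain remains statistically exact.
Mesoscopic densities are estimated by a top-hat window of radius $r$
(default $0.1$) in $x$, averaged vertically; a Gaussian window is available
(`kernel = "gaussian"`) since the precise smoothing kernel used for the
published kymographs is not stated. Default lattice spacing for desk-scale
runs is $h = 0.025$; at strong activity the published comparisons use
$h = 0.01$, which is hours-scale and kept behind explicit arguments.

## Deterministic integration

`integrate_pde()` advances the 1D equations with a first-order
finite-volume scheme: two-point centered diffusive fluxes, and either
upwinded (`scheme = "upwind"`, default) or centered (`scheme = "centered"`)
advective fluxes, forward Euler in time with
$\Delta t = \mathrm{cfl} \cdot \min\{\Delta x^2 / (2\max[d_s + \rho\mathcal{D}]),
\Delta x/(2\max|v|)\}$ and halving on positivity violation. Species means
are conserved to machine precision by the conservative flux form.

The upwind flux is robust at sharp interfaces but carries $O(\Delta x)$
numerical diffusion that biases measured propagation speeds by several
percent at $\Delta x = 0.05$; the centered flux is second-order accurate in
space and is the package's protocol for quantitative speed measurements
(halving $\Delta x$ then changes measured speeds by well under 1%). Both
schemes agree as $\Delta x \to 0$.

Initial conditions (`make_initial_condition()`) are the homogeneous state
plus mean-subtracted uniform noise (default absolute amplitude $10^{-3}$)
and/or the real part of a dominant eigenvector at an admissible wavenumber
$q = 2\pi k/L$ (default amplitude $10^{-2}$); the left/right branch is the
one whose linear phase velocity $-\mathrm{Im}\,\lambda/q$ is negative/
positive, and the "pair" kind superposes both, seeding counter-propagating
waves. These amplitudes are package choices: the published values live in
supplementary material that is not part of the sources used here. At the
reference traveling-wave state point ($\mathrm{Pe}=7.5$, $\phi_a=0.36$,
$\phi_p=0.3$) our linearization puts the gravest $L=25$ mode marginally on
the stable side (growth $-0.004$), while the traveling attractor coexists
with the homogeneous state; seeding therefore uses the least-stable mode at
finite amplitude (`force_mode = TRUE`), amplitude $0.05$, which reliably
selects the traveling branch.

## Linear stability

A plane-wave perturbation $\delta A_\sigma e^{\lambda t + iqx}$ of the
homogeneous state leads to a $3\times 3$ eigenvalue problem whose matrix is
assembled from analytic derivatives of the transport coefficients
(`stability_matrix()`). At $q = 0$ the spectrum is exactly $\{0, 0, -2\}$:
two conserved fields, and $m$ relaxing at rate 2. The matrix is not printed
in the source material; it is derived from the equations and validated
entry-wise (to $10^{-6}$ and better) against a Richardson-extrapolated
numerical Jacobian of the discretized right-hand side, and its eigenvalues
are validated against fitted linear-response growth rates of the time
stepper to $10^{-2}$ relative error. (The printed perturbation form
contains an obvious typo, $e^{\lambda t + iqxt}$; the standard plane wave is
used.)

The spinodal is traced by bisection along rays from an interior unstable
point, using the continuous-$q$ supremum of the dominant growth rate
(thermodynamic limit); rays whose neutral crossing happens on the domain
boundary of the composition triangle are discarded. Bogdanov–Takens
(codimension-two) points, where the dominant eigenvalue switches between
real and complex along the spinodal, are located by angular bisection.

## Phase coexistence

For stationary phase-separated profiles the integrated fluxes vanish, which
slaves the magnetization, $m = \partial_x\rho / [\mathrm{Pe}(1-\rho)]$, and
the passive density, $\rho_0 = \nu(1-\rho)$ with $\nu = \phi_p/(1-\phi)$ for
the global profile. Substituting into the stationary magnetization balance
and integrating once collapses the system to
$g_0(\rho) + \Lambda(\rho)(\partial_x\rho)^2 - \kappa(\rho)\partial_x^2\rho
= \text{const}$, with
$$
g_0 = \mathrm{Pe}\, d_s(\rho)\,[(1+\nu)\rho - \nu] - \frac{2}{\mathrm{Pe}}\log(1-\rho),
\quad
\Lambda = \frac{1}{\mathrm{Pe}}\left[\frac{s - d_s}{(1-\rho)^2} - \frac{\mathcal{D}}{1-\rho}\right],
\quad
\kappa = \frac{d_s}{\mathrm{Pe}(1-\rho)} .
$$
These closed forms were derived by hand for this package (the published
explicit forms are in unavailable supplementary material) and are locked in
by a residual oracle: along an independently relaxed stationary profile of
the time stepper, $g$ is constant to a relative standard deviation of
$4\times10^{-4}$, while flipping the sign convention of $\Lambda$ degrades
this by more than three orders of magnitude.

The coexisting densities follow from a generalized common-tangent
construction. An integrating factor $\mu = R'(\rho)$ with
$\mu'/\mu = -(2\Lambda + \kappa')/\kappa$ turns the gradient terms into an
exact second derivative of $R(\rho)$; note this differs from the simpler
prescription $R''/R' = -\Lambda/\kappa$, which fails the equilibrium
sanity check $\Lambda = -\kappa'/2 \Rightarrow R = \rho$. With
$\Phi'(R) = g_0$, coexistence requires equal $g_0$ in both phases and the
equal-intercept (common tangent) condition on $\Phi(R)$. Numerically,
$\ln\mu$ is accumulated by trapezoidal quadrature on a grid geometrically
refined toward full packing, the tangent residual is evaluated by adaptive
quadrature (the weight $\mu$ grows like $(1-\rho)^{-4}$, which a fixed grid
cannot resolve at strong activity), and the vapor density is bracketed by a
geometric scan from the feasibility edges — the root hugs the lower edge at
large Pe and the critical point at large $\nu$. Coexistence exists for
$\nu$ below a critical value $\nu^\*(\mathrm{Pe})$ computed by maximizing
the explicit $\nu(\rho)$ along the locus $g_0'(\rho;\nu) = 0$ (the
dependence on $\nu$ is linear with positive slope, so this boundary is
exact). The stationary interface profile follows by quadrature of the first
integral $\tfrac12 \kappa\mu (\partial_x\rho)^2 = \Psi(\rho)$, where $\Psi$
is the excess of $\Phi$ over its tangent; the gauge is $\rho(0)$ at the
mid-density.

Validation: at $\mathrm{Pe}=20$, $\nu=0.25$ the predicted binodal pair
$(0.2320, 0.9928)$ matches the long-time plateau densities of an
independently relaxed $L = 2$ profile within the expected finite-size
corrections (0.8% and 0.04%), and the interface's peak magnetization
(0.7375) matches the relaxed profile's (0.7373).

## Traveling waves

In the co-moving frame $z = x - ct/L$ a steady profile solves a nonlinear
BVP with unknown speed. `solve_finite_L()` discretizes the three-species
system with second-order centered fluxes on the periodic grid and solves
profiles-plus-speed by damped Newton (Armijo line search on the residual
2-norm, Levenberg–Marquardt fallback) with a sparse Jacobian assembled by
colored finite differences; the dense rows (species means, translational
gauge $\rho(z_1) = \phi$) are entered analytically. Discrete conservation
identities make two residual rows exactly dependent, so one row per
conserved field is dropped; the orientation-flip balance $\int m\,dz = 0$
then emerges automatically rather than being imposed. The printed mass
conditions are read as domain averages (dimensional consistency).

For $L \gg 1$, traveling states consist of $O(L)$ smooth "outer" regions
joined by $O(1)$ interfaces that coincide, at leading order, with the
stationary liquid–vapor interfaces and hence connect binodal endpoints
along tie lines. Eliminating $m$ order by order in $1/L$ leaves two
equations for $(\varrho_a, \varrho_0)$ with an effective nonreciprocal
cross-coupling proportional to $\mathrm{Pe}^2$. `solve_outer()` solves this
outer problem on the unit interval:

* **Smooth regime** (no interface): periodic boundary conditions, species
  means, and a translational gauge.
* **Single interface**: the interface sits at the domain boundary with
  Dirichlet values at the vapor (left) and liquid (right) endpoints of a
  binodal tie line. The equations are solved in first-order ("box") form,
  with the two flux integration constants as explicit unknowns — along a
  smooth piece the integrated equations say flux = const at every face,
  which conditions the Newton system far better than differencing the
  fluxes. The tie-line ratio of the interface is *not* fixed at the global
  $\nu = \phi_p/(1-\phi)$: counting equations shows a fixed ratio
  overdetermines the problem by one, and converged finite-$L$ waves indeed
  select interface ratios far from the global one (0.52 versus 0.88 at the
  reference point). The ratio is therefore closed by the passive-mass
  constraint through a guarded secant iteration, each inner solve being a
  square fixed-ratio problem.
* **Two interfaces** (`solve_outer_two_interface()`): when the profile's
  composition path would cross the coexistence region, a second interface
  appears on its own tie line; its position $z^\*$ and ratio are Newton
  unknowns, the flux constants are global (flux continuity through the
  quasi-static inner regions), and the primary ratio is again closed by the
  passive mass. A failed single-interface solve is re-seeded by splitting
  at the steepest interior gradient (`insert_interface()`).

Newton needs a nearby seed: in practice a relaxed time-stepping attractor,
a previously converged wave at neighboring parameters (continuation), or a
finite-$L$ solution with the inner region excised
(`outer_seed_from_wave()`). A small library of such converged coarse
profiles ships in `inst/extdata/outer_wave_seeds.json` (package-generated
initial guesses; every reported solution is re-converged from the equations
at run time). Direct time stepping of the outer equations
(`outer_time_step()`) is only meaningful at locally stable compositions:
inside the spinodal the reduced system is scale-free unstable
(backward-parabolic), which is also why its stationary profiles must be
computed as BVPs.

At the reference point the finite-$L$ speeds converge monotonically to the
outer value ($c_L = -2.030, -1.967, -1.949$ at $L = 25, 50, 100$ against
$c_\infty = -1.942$), and the finite-size branch terminates in a fold near
$L \approx 10$ — below it no traveling solution exists at these volume
fractions. An exact argument from the integrated total-density balance
forbids moving profiles with two bulk plateaus of different densities
(`no_traveling_ps_check()` asserts this on converged solutions): traveling
phase separation is impossible, and slow traveling states instead carry a
single plateau plus smooth structure.

## Classifying long-time states

`classify()` reduces a trajectory to two metrics — the approximate speed
$\tilde c = \lVert\partial_t\rho_\sigma\rVert_2 / \lVert\partial_x\rho_\sigma\rVert_2$
(all species stacked; this equals the wave velocity for an exact traveling
profile) and the distance from uniformity
$d_H = (\sum_\sigma \lVert\rho_\sigma - \phi_\sigma\rVert_2)^{1/2}$ (outer
square root over a *sum of norms*, reproduced exactly as printed even
though its units are unusual) — and applies threshold rules on an
observation window: homogeneous if $\sup d_H < 0.05$; phase-separated if
structured but $\sup\tilde c < 0.01$; traveling if $\tilde c(t^\*) \ge 0.01$
with drift $\sup|\tilde c'| < 10^{-5}$; else counter-propagating. Norms are
grid-weighted ($\sqrt{\sum f^2\,\Delta x}$; the weighting cancels in
$\tilde c$), $\tilde c'$ uses a five-point moving average before
differencing, and the time derivative uses stored frames, so the default
sampling interval is 1 or finer. The printed protocol runs to
$t^\* \ge 700$ with a 500-long window; the strongly separated fixtures at
$L = 2$ settle by $t \approx 20$, so scaled-down runs (final time 30,
window 15) are used in the tests, with labels stable under doubling.

## Problem sizes and limitations

The test suite and the acceptance script run at desk scale by choice:
PDE fixtures at $\Delta x = 0.01$ ($L = 2$) and $\Delta x = 0.05$
($L = 25$), lattice comparisons at $h = 0.02$–$0.025$ with tens of
thousands of particles, outer solves at $N = 256$ refined to $N = 1024$,
and finite-$L$ waves at $N$ between 500 and 3200. The generator emulates
the study conditions (volume fractions, Péclet numbers, seeds) but not
every feature of the published computations: the supplementary
initial-condition amplitudes and the precise time-stepping flux of the
original study are unavailable, and measured propagation speeds at finite
$\Delta x$ depend on that choice at the few-percent level (the upwind and
centered options bracket it; the centered protocol is grid-converged).
The four large-$L$ reference speeds are computed at volume fractions that
are documented estimates: the published values are figure annotations not
present in the text sources, and only the first column's coordinates could
be cross-identified (the flagship state point, whose computed outer speed
reproduces the printed value to 0.4%). Two-dimensional pattern formation,
fluctuating corrections to the hydrodynamic limit, and stability analysis
of inhomogeneous base states are out of scope.
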