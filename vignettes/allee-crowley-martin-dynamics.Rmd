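---
title: "Dynamics and pattern formation in a predator-prey model with Allee effect and Crowley-Martin response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics and pattern formation in a predator-prey model with Allee effect and Crowley-Martin response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleeCM)
```

## The model

`alleeCM` analyses a two-species predator-prey system in which prey growth
suffers a multiplicative Allee effect and predation follows the
Crowley-Martin functional response, which lets predators interfere with one
another even while handling prey. After scaling prey by the carrying
capacity, predators by carrying capacity times conversion efficiency, and
time by the intrinsic growth-rate scale, the non-spatial model is

$$\frac{dx}{dt} = x(1-x)(x-l) - \frac{\beta x y}{(1+ax)(1+by)}, \qquad
  \frac{dy}{dt} = \frac{\beta x y}{(1+ax)(1+by)} - d y,$$

with prey $x$, predator $y$, Allee threshold $l$, capture rate $\beta$,
handling coefficient $a$, interference coefficient $b$ and predator death
rate $d$ (all dimensionless, all positive except $l$). The spatial variant
adds Fickian diffusion $d_1\nabla^2 x$, $d_2\nabla^2 y$ on a square domain
with zero-flux boundaries. `nondimensionalize()` maps dimensional
parameters onto these groups and documents the variable scaling.

The Allee effect is *strong* for $0 < l < 1$ — prey below the threshold
density collapse even without predation — and *weak* for $-1 < l \le 0$.
Values $l \le -1$ lie outside the weak-Allee range; `model_params()` rejects
them unless `permissive = TRUE`, because one published phase portrait uses
such a value and we want to be able to reproduce the attempt (it does not, in
fact, reproduce: see "Degenerate and disputed inputs" below). With
`allee = FALSE` the growth term reverts to logistic $x(1-x)$ and the whole
tool chain — equilibria, stability, Turing analysis, simulation — operates
on that variant instead; the pattern-sequence studies use it.

The denominator is evaluated in the factored form $(1+ax)(1+by)$, which is
algebraically identical to $1+ax+by+abxy$ but matches the factorization in
which the Jacobian entries are naturally written; the expanded form is kept
in the test suite as an oracle.

## Equilibria

Besides the boundary states $E_0=(0,0)$, $E_1=(1,0)$ and (for $0<l<1$)
$E_2=(l,0)$, interior equilibria satisfy both nullclines. Eliminating

$$y^*(x) = \frac{\beta x - (1+ax)d}{b d (1+ax)}$$

reduces the Allee model to a quartic
$Q(x) = abx^4 + b\{1-a(1+l)\}x^3 + \{lab - b(1+l)\}x^2 + (lb+\beta-ad)x - d$,
and the logistic variant to a cubic. `coexistence_equilibria()` keeps the
positive real roots whose $y^*$ is strictly positive — this positivity
filter subsumes the side condition $\beta > ad$. Depending on parameters
there are zero to three interior states, and the package reproduces every
published nullcline-multiplicity panel from the figure-caption parameter
registry (`get_fixture()`).

Numerics: roots come from `polyroot()` (companion-matrix eigenvalues),
followed by a *safeguarded* Newton polish — any proposed step larger than
`1e-6` is rejected, because a large step means $Q' \approx 0$, i.e. a
multiple root, where Newton would scatter an accurately computed double pair.
Near-duplicate roots (within `1e-7`) merge into one equilibrium with
`multiplicity = 2`. A second, tangency-aware merge pass handles fold points
parameterized by finitely printed critical values: a pair of roots closer
than `1e-3` whose midpoint residual $|Q|$ is at coefficient rounding level
(below $10^{-10}$ times the coefficient scale) cannot be distinguished from
a tangency at the available parameter precision and is reported as one
double root. Genuinely distinct roots have midpoint residuals many orders of
magnitude larger, so the pass cannot collapse them.

## Local stability and the boundary spectrum

`classify_equilibrium()` applies the trace/determinant rules to the exact
reaction Jacobian: saddle iff $\det J < 0$, stable/unstable by the trace
sign, focus/node by the discriminant, and `"marginal"` within tight
tolerances of a Hopf ($|\mathrm{tr}| < 10^{-9}$, $\det > 0$) or fold
($|\det| < 10^{-12}$) point.

Two Jacobian facts deserve emphasis because they are easy to get wrong by
symbol-pushing, and both are pinned by finite-difference tests:

* At an interior equilibrium,
  $J_{11} = x(1+l-2x) + \beta a x y/((1+ax)^2(1+by))$ with a **plus** sign
  on the predation term: the saturating response makes effective prey
  self-regulation *less* negative, which is precisely what permits
  $J_{11} > 0$ and hence diffusion-driven instability (prey act as the
  activator).
* At the threshold state $E_2 = (l, 0)$ the prey-axis eigenvalue is
  $+l(1-l) > 0$: the strong-Allee threshold repels along the prey axis, so
  $E_2$ is a saddle when $\beta l < d(1+al)$ and an unstable node
  otherwise — never an attractor. `boundary_eigenvalues()` returns the
  closed forms for all three boundary states.

## Bifurcations in the capture rate

**Hopf.** `hopf_critical_beta()` follows one coexistence branch across a
bracket in $\beta$ (continuation by nearest prey level; a change in branch
count raises a collision error) and locates the trace zero crossing with
`uniroot`. At the returned $\beta_c$ the eigenvalues are $\pm i\omega_0$
with $\omega_0=\sqrt{\det J}$ and the focus flips between stable and
unstable. The transversality value is the **total** derivative of the trace
along the branch, estimated by central finite differences: the equilibrium
coordinates move with $\beta$ (through the quartic's $\beta$-dependent
coefficient), so a partial-derivative formula that freezes $(x^*,y^*)$ does
not measure the actual crossing speed. No normal-form (first Lyapunov
coefficient) computation is attempted; criticality is observed empirically
through limit-cycle detection on the unstable side.

**Fold.** `fold_beta()` bisects on the coexistence count (60 bisections)
and refines with Newton on the $2\times 2$ system $Q = Q' = 0$ in
$(x, \beta)$, using $\partial Q/\partial\beta = x$. Reported to full double
precision; the test suite reproduces the two published tangency values
(10.1267155062337 and 11.494054912906) to machine-level agreement.

## Trajectories, cycles, separatrices, basins

`integrate_model()` wraps `deSolve::ode` (Dormand-Prince 4(5) by default,
`rtol = 1e-8`, `atol = 1e-10`). The model is only meaningful on the closed
positive quadrant, so the right-hand side is evaluated at states floored at
zero and output components in $[-100\,\mathrm{atol}, 0)$ are clipped to
zero; anything more negative, or any magnitude above $10^6$, errors. The
clip floor is tied to `atol` because an adaptive solver legitimately
undershoots by about its absolute tolerance while relaxing onto the
extinction state; a fixed floor of $10^{-12}$ would reject correct
trajectories.

`detect_limit_cycle()` integrates from a small radial offset off the
equilibrium and interpolates upward crossings of the Poincaré section
$x = x^*$. After discarding 200 transient crossings (a cap of 2000, both
configurable), the cycle is declared found when successive crossing
predator levels converge (relative change below $10^{-4}$) to a value
bounded away from $y^*$ (2% of $y^*$); convergence onto $y^*$ itself is a
spiral-in and reports `found = FALSE`.

`separatrix()` reconstructs the stable manifold of a saddle by
backward-time integration from $\pm 10^{-6}$ along the stable eigenvector,
using `lsodar` with root-triggered termination on leaving the phase-plane
box or when the backward flow stalls near another equilibrium (a backward
integration from a saddle can spiral into an unstable focus, where step
sizes would otherwise collapse). `basin_classify()` labels initial states
by the attractor their endpoint approaches, with `"unresolved"` for
everything else — in the bistable strong-Allee regime this exhibits
extinction and coexistence basins separated by the computed manifold.

## Linear spatial theory

For perturbations $\propto e^{\mu t + i k\cdot\xi}$ of the unique
coexistence state, the growth rates solve
$\mu^2 + \alpha_k \mu + \beta_k = 0$ with
$\alpha_k = k^2(d_1+d_2) - \mathrm{tr}\,J$ and
$\beta_k = d_1 d_2 k^4 - (d_1 J_{22} + d_2 J_{11})k^2 + \det J$
(`dispersion()`). Turing instability requires the state to be stable
without diffusion ((i) $\mathrm{tr}\,J<0$, (ii) $\det J>0$) yet have
$\beta_k < 0$ somewhere. `turing_conditions()` applies condition (iv) in
the *signed* form $d_1J_{22}+d_2J_{11} > 2\sqrt{d_1 d_2 \det J}$, which
given (ii) entails (iii) $d_1J_{22}+d_2J_{11}>0$; the unsigned quadratic
comparison alone would also admit parameter sets where the $\beta_k$
parabola dips negative only at unphysical negative $k^2$. With this
convention `turing_unstable = (i) & (ii) & (iv)` and the unstable band —
the real roots of $\beta_k$ in $k^2$, around the minimizer
$k^2_{\mathrm{crit}} = (d_1J_{22}+d_2J_{11})/(2d_1d_2)$ — is nonempty
exactly when (iv) holds.

$k$ is treated as continuous (large-domain approximation): the study
protocol uses a $200\times200$ domain whose mode spacing is much finer than
the unstable band, and no domain length is prescribed for mode
quantization. `turing_scan()` maps the Turing space over any two parameters,
reporting `"indeterminate"` where the coexistence state is absent or
non-unique, since the linear analysis presumes a unique homogeneous state.

## Reaction-diffusion simulation

`simulate_pattern()` integrates the 2-D system with explicit Euler in time
and a five-point Laplacian in space, zero-flux boundaries implemented by
mirrored ghost cells (the cell-centred second-order discretization of
$\partial/\partial n = 0$; the ghost equals the boundary cell itself, so a
constant field has an exactly zero Laplacian and diffusion moves no net
mass). The stepper is compiled (Rcpp) for speed; a vectorized R reference
step (`pde_step()`, `laplacian_neumann()`) defines the scheme and the test
suite checks the two agree to rounding. The CFL-type bound
$dt \le h^2/(4\max(d_1,d_2))$ is enforced at configuration time. Negative
values (explicit Euler can undershoot near sharp fronts) are clipped to
zero and counted; the count is returned as a quality metric rather than an
error.

Defaults mirror the study protocol: $200\times200$ grid, $h=1$, $dt=0.01$,
horizon $t=5000$, and the initial condition a seeded uniform random
perturbation of the homogeneous coexistence state. The protocol specifies
only a "small" perturbation; the package fixes 1% of the equilibrium value
($U\sim\mathrm{Uniform}(-1,1)$ i.i.d. per cell, amplitude recorded in the
output manifest) as its reproducible default. Runs with equal seeds are
bitwise identical.

`pattern_summary()` reduces a field to moments plus a connected-component
morphology: the deviation from the spatial mean is thresholded at zero,
4-connected components of each sign are labelled (compiled flood fill), and
the minority-area sign is examined. Many compact components (mean
circularity $4\pi A/P^2$ above 0.55, at least 8 components, components
under 4 cells ignored) read as hot or cold spots by sign; few elongated
components read as stripes/labyrinthine; other combinations as mixtures.
The circularity threshold was calibrated once on the constructed
`morphology_fixture()` fields, which score about 0.62 (spot lattices) vs
0.45 (sinusoidal bands) across grid sizes. The classifier is a heuristic
summary of what the source work assesses visually; the quantitative
polarity statement — prey skewness negative for hole-dominated patterns,
positive for spot-dominated ones — relies only on the moments.

## Problem sizes and what the tests show

The full protocol ($200\times200$, $t=5000$) is supported but slow on one
core, so the regression and acceptance suites run the package's desk-scale
configuration: $64\times64$ grids with the same $h$ and $dt$. Horizons are
chosen from the linear theory rather than fixed blindly: the reference
Allee pattern set has a maximal growth rate of only $\approx 2\times10^{-3}$
per time unit, so a 1% perturbation saturates near $t\approx2000$, and the
suite runs it to $t=2500$, asserting both the inhomogeneous variance level
and its plateau (stationarity). The two logistic-variant polarity sets grow
faster ($\approx 0.8$–$1.7\times10^{-2}$) and are run to $t=1500$ with the
same plateau check. A single-cosine-mode experiment verifies the measured
amplitude growth rate against the dispersion relation to within a few
percent, tying the simulator to the linear theory quantitatively.

Passing these tests shows the pipeline is internally consistent —
equilibria, spectra, bifurcation values, dispersion and the nonlinear
simulation agree with each other and with the published figure-level facts
(equilibrium counts, fold values, pattern polarity). The synthetic
perturbations emulate none of the structure of real ecological data — no
demographic stochasticity, measurement error, habitat heterogeneity or
boundary irregularity — so the results say nothing about parameter
identifiability or fit to field populations.

## Degenerate and disputed inputs

* The weak-Allee portrait with $l=-2$ (registered as `fig4`, permissive
  mode) does **not** reproduce its published description: the quartic has a
  complex pair, leaving a single interior equilibrium rather than three.
  The fixture keeps the verbatim caption annotation but is excluded from
  count regressions.
* At fold points parameterized by printed critical values, the collided
  pair is reported as one equilibrium of multiplicity 2 (see the merge
  policy above), matching how the source counts them.
* The simulation prose denotes the capture rate by $c$ in places where the
  captions use $\beta$; the fixture registry treats them as the same
  parameter.
* Zero or non-unique coexistence states make Turing reports
  "indeterminate" and `simulate_pattern()` an error, not a silent default.

## Limitations

No two-parameter continuation, normal forms, codimension-two points, time
delays, stochastic forcing, cross-diffusion, travelling-wave analysis, or
non-square/1-D/3-D domains; the explicit Euler scheme is first-order in
time and conditionally stable, chosen to match the study protocol rather
than for efficiency.
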