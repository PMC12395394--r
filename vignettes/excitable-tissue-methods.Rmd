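---
title: "Excitable vertex-model dynamics: model, methods and design choices"
author: "excitissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitable vertex-model dynamics: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`excitissue` simulates a confluent epithelial monolayer as a two-dimensional
vertex model on a torus. Cells are polygons, vertices are the degrees of
freedom, and each cell--cell junction is an excitable mechanical unit. The
passive mechanics derive from the energy

$$H = \frac{K}{2}\sum_\alpha \left(A_\alpha - A_0\right)^2
    + \Lambda \sum_{\langle i,j\rangle} l_{ij},$$

an area elasticity over cells plus an interfacial tension over junctions.
Vertices follow overdamped dynamics,
$\mu\,\dot r_i = -\partial H/\partial r_i + F^{\mathrm{act}}_i$, with a
length-proportional active force
$F^{\mathrm{act}}_i = -\sum_{\langle i,j\rangle}\Gamma_{ij}(t)\, l_{ij}\,
\partial l_{ij}/\partial r_i$: an active junction pulls its endpoints
together with force $\Gamma_{ij} l_{ij}$. Length-dependent active tension
makes the induced strain independent of the initial edge length, as observed
when junctional contractility is activated optogenetically.

Junctions are viscoelastic: rest lengths remodel toward the current length,
$\dot l^0_{ij} = -k_L\,(l^0_{ij} - l_{ij})$, which continuously relaxes the
junctional strain $\varepsilon_{ij} = (l_{ij} - l^0_{ij})/l^0_{ij}$. This
remodeling applies to every junction regardless of its excitability state;
nothing in the state rules exempts any state from turnover.

The excitable feedback is a three-state automaton per junction,
coarse-graining stretch-triggered contractility (e.g. ERK-mediated myosin
recruitment) and its inhibitors:

* **inactive** ($\Gamma = 0$): activates when $\varepsilon \ge
  \varepsilon_{on}$;
* **active** ($\Gamma = \Gamma_0$): becomes refractory after $\tau_{act}$;
* **refractory** ($\Gamma = 0$): cannot activate; becomes inactive after
  $\tau_{ref}$.

The threshold comparison is *inclusive* ($\ge$). The distinction from a
strict inequality is immaterial at time-step resolution, but a fixed
convention is needed for reproducibility, and the same convention is used in
the 2D tissue and the 1D effective model.

## Units and default parameters

Forces are measured in $K A_0^{3/2}$, lengths in $\sqrt{A_0}$, and time in
$t_0 = \mu/(0.636\,K\sqrt{A_0})$; with the default $\mu = 0.636$ the time
unit is 1. Defaults (`mech_params()`, `excit_params()`): $K = 1$, $A_0 = 1$,
$\Lambda = 0.1$, $\mu = 0.636$, $\Gamma_0 = 0.5$, $k_L = 1$,
$\varepsilon_{on} = 0.1$, $l_{T1} = 0.01$, $\Delta t = 0.01$. The activation
and refractory periods have no single canonical value -- they are the axes
of the phase diagrams -- so `excit_params()` defaults to
$\tau_{act} = \tau_{ref} = 1$ and experiments set them explicitly. The ratio
$\Delta = \tau_{ref}/\tau_{act}$ controls wavefront geometry.

## Integration and per-step ordering

A forward-Euler step of length $\Delta t$ performs, in this fixed order:

1. force evaluation (area elasticity + line tension + active tension);
2. position update $r_i \leftarrow r_i + (\Delta t/\mu) F_i$, reduced into
   the box;
3. rest-length update $l^0 \leftarrow l^0 - \Delta t\, k_L (l^0 - l)$;
4. state-machine update: timers decrement; active$\to$refractory and
   refractory$\to$inactive on expiry; inactive junctions at or above
   threshold strain activate. All transitions are computed from the
   pre-step state and applied simultaneously, so junction indexing cannot
   bias the dynamics, and a junction leaving the refractory state cannot
   re-activate within the same step;
5. T1 checks.

Any fixed ordering is acceptable at small $\Delta t$; this one follows the
"integrate, then react" reading of the update cycle. Realized state
durations are quantized to multiples of $\Delta t$; the experiments use
durations that are multiples of the step. A convergence test verifies that
halving $\Delta t$ does not change tracked observables beyond their
tolerance.

## T1 transitions

A junction shorter than $l_{T1}$ collapses to a transient 4-fold vertex that
is resolved immediately into the transverse connectivity: the two cells that
shared the edge each lose a side, the two end cells each gain one, and $V$,
$E$, $C$ are conserved. The new junction is placed perpendicular to the old
one, centered at its midpoint, with $l = l^0 = 1.5\,l_{T1}$, inactive with
$\Gamma = 0$. Only the new junction's length/state is prescribed by the
model; the perpendicular-bisector placement is this package's choice of
resolution geometry. A swap that would create a two-sided cell is skipped
and counted in `tissue$stats$t1_skipped`.

## Tissue generation

**Ordered tissues** are pointy-top honeycombs of regular unit-area hexagons
(edge $a = (4/27)^{1/4} \approx 0.6204$), built on an exact integer lattice
so shared vertices merge without floating-point tolerance. The requested box
is adjusted to the nearest commensurate `ncols x nrows` grid (`nrows` even
for periodicity) and the adjustment is reported. The 260-cell reference
tissue has 780 junctions and 520 vertices in a box $\approx 13.97 \times
18.61$. By symmetry the lattice is an equilibrium of $H$; construction
verifies the residual force numerically.

**Disordered tissues** start from seeded uniform random points, take a few
Lloyd (centroidal Voronoi) iterations, tessellate with a periodic Voronoi
construction (half-plane clipping against the periodic images of each
point's neighbors), merge coincident polygon corners by periodic
single-linkage clustering at $10^{-6}$, and then relax the network to
mechanical equilibrium (all $\Gamma = 0$, maximum residual force below
$10^{-6}$, far beneath the $\Lambda = 0.1$ force scale) before zeroing all
strains. T1 events during relaxation are allowed. The whole pipeline is a
pure function of `(n_cells, box, seed)`. The generation protocol is this
package's own (the emergent-dynamics results do not depend on how the
disordered equilibrium was produced, only on its geometric heterogeneity);
quantitative properties of a particular disordered ensemble -- e.g. the
junction-length distribution -- are therefore not pinned to any external
reference.

## The effective three-junction model

The 1D reduction keeps a central junction ($l_1$, tension $\Lambda_1$)
flanked by two mirror-symmetric outer junctions ($l_2$, tension
$\Lambda_2$) between fixed walls, $l_1 + 2l_2 = 3L$, with energy

$$H_{\mathrm{eff}} = \frac{k}{2}(l_1 - L)^2 + k(l_2 - L)^2
  + \Lambda_1 l_1 + 2\Lambda_2 l_2 + \frac{\Gamma_1}{2} l_1^2 + \Gamma_2 l_2^2.$$

A literal per-length gradient flow $\mu \dot l_i = -\partial
H_{\mathrm{eff}}/\partial l_i$ would not preserve the wall constraint, so
the integrated degree of freedom is the internal node position: by mirror
symmetry the two nodes are equivalent and the model reduces to a single ODE
in $x = l_2$ with $l_1 = 3L - 2x$ and $\mu \dot x = -\partial
H_{\mathrm{eff}}/\partial x$. This choice is not arbitrary: with the central
junction active and $k_L = 0$ it gives the outer strain
$\varepsilon_2(t) = \frac{\Gamma_0}{3+2\Gamma_0}\left(1 -
e^{-2(3+2\Gamma_0)t}\right)$, whose threshold-crossing time is exactly the
closed-form propagation threshold

$$\tau_p = \frac{1}{2(3+2\Gamma_0)}
  \ln\frac{\Gamma_0}{\Gamma_0 - (3+2\Gamma_0)\varepsilon_{on}},$$

so the numeric model and the analytic theory agree by construction rather
than by fit. $\tau_p = 0$ at $\varepsilon_{on} = 0$ (activity always
propagates) and $\tau_p = \infty$ for $\varepsilon_{on} \ge
\Gamma_0/(3+2\Gamma_0)$.

Reactivation of the central junction at the end of its refractory period
(assessed at $t = 2\tau$, the simulated horizon, with the inclusive
threshold) obeys $A e^{-6\tau} - B e^{-6(2+\Gamma_0)\tau} >
\varepsilon_{on}$ with

$$A = \frac{2\Gamma_0}{3+\Gamma_0}\left(1 - e^{-2(3+\Gamma_0)\tau_p}\right) e^{6\tau_p},
\qquad
B = \frac{2\Gamma_0}{3+2\Gamma_0}\left(1 - e^{-2(3+2\Gamma_0)\tau_p}\right) e^{2(3+2\Gamma_0)\tau_p}.$$

The exponent of the second term is read as $6(2+\Gamma_0)\tau$: with
$\Gamma_0 = 1$ the left-hand side is then the cubic $Ay - By^3 -
\varepsilon_{on}$ in $y = e^{-6\tau}$, which is the form in which the
inequality is tractable. `reactivation_range()` solves it numerically
(dense scan plus `uniroot`, tolerance $10^{-10}$) for the window $(\tau_1,
\tau_2)$ above $\tau_p$. At $\Gamma_0 = 1$ the window is nonempty exactly
for $0.077 < \varepsilon_{on} < 0.2$, and at $\varepsilon_{on} = 0.1$ the
onset sits $\tau_1 - \tau_p = 0.003$ above the propagation threshold.

The ODE is integrated with forward Euler at $\Delta t = 10^{-3}$ (time unit
$\mu/k$). Numeric thresholds (`eff_critical_tau()`) are found by bisection;
propagation is monotone in $\tau$ and bisected directly, while reactivation
occurs on a window, so an ascending scan brackets its onset first. Because
timers quantize durations to the step, thresholds are meaningful only to
about $2\Delta t$, and that is the agreement demanded of the
analytic/numeric cross-check. For $\tau_1$ the package takes the analytic
inequality at $k_L = 0$ and the simulated outcome at $k_L > 0$; the swept
remodeling range defaults to $k_L \in [0, 1]$.

## Observables and classification

`run_simulation()` samples junction-state fractions and the total strain
$\sum \varepsilon_{ij}$. A run is **quiescent** if the maximum active
fraction never exceeds $\theta_{prop} = 0.1$; otherwise it is a **wave** if
activity persists and a **pulse** if it dies. The same $\theta_{prop}$ is
used for ordered and disordered tissues (a single operational definition,
also used as the boundary in `critical_kL()` bisection). "Final" activity is
the mean over the last 10% of the horizon rather than the last sample: wave
states oscillate, and a point sample could alias with the oscillation
phase. Sweep runs use the horizon $t = 20$, by which wave states on the
reference tissues have reached their oscillatory steady state and pulses
have decayed.

`measure_wavelength()` bins the active-junction indicator radially about
the seeding point (bin width: the median junction length, one hexagon edge
on ordered tissues), segments the mean-activity profile into rings --
contiguous runs of bins with active fraction $\ge 0.5$, a threshold that
separates the broad active bands from the low-activity dips between them --
and averages the spacing of ring centers over snapshots. Radii beyond half
the smaller box side are discarded, so snapshots must be taken while the
pattern is still expanding; after the wavefront wraps the periodic box,
self-interference corrupts any radial estimator. A run-presence estimator
(any active junction in a bin) was rejected because stray activations in
the inter-ring dips merge adjacent rings. Front-speed-times-period is a
possible cross-check estimator; the radial one is canonical here.

## Problem sizes used in the checks

The automated checks run the tissue experiments at their natural desk
scale, chosen as the package's reference configurations: 260-cell ordered
and 208-cell disordered tissues for the phase points and the critical-rate
trend (10 seed junctions, 5 bisection iterations), and a 900-cell ordered
tissue (box $\approx 32 \times 28$) for wavefront-geometry runs at $\Delta
t = 0.05$, where wavelengths are measured at $t \le 10$ from snapshots at
$t = 8.5$ and $10$, before the front wraps. The wavelength--$\Delta$ trend
uses $\Delta \in \{0.2, 0.3, 0.4\}$, inside the wave regime at $k_L = 0.5$,
$\tau_{act} = 2$; by $\Delta \gtrsim 0.6$ re-emission fails and a solitary
pulse remains.

## What the generators do and do not emulate

Synthetic tissues capture the two geometric features the model's behavior
hinges on: uniform packing (ordered honeycombs) versus heterogeneous
junction lengths and polygon sidedness (equilibrated Voronoi networks).
They do not emulate curved or open boundaries, cell division or extrusion,
spatial gradients in mechanical properties, or measured epithelial geometry
statistics; passing checks on these tissues demonstrate the model's
emergent dynamics, not quantitative agreement with any particular real
tissue.

## Known limitations

* Contractility is binary per junction; graded activity and explicit
  kinase/inhibitor dynamics are outside scope.
* Spiral-pair runs (row-plus-refractory seeding at $\Delta > 1$) are
  produced, but spiral topology is recognized by eye, not detected
  automatically.
* The absolute wavelength depends on the estimator's binning; only the
  synthetic-ring oracle and monotonicity in $\Delta$ validate it.
* Forward Euler with a fixed step is the only integrator; the default steps
  were validated by halving, not by adaptivity.
* At $k_L > 0$ the propagation/reactivation boundaries exist only
  numerically; the closed forms hold at $k_L = 0$.
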