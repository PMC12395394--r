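# excitissue

Mechanically excitable epithelial tissue, simulated with a vertex model.

Many epithelia display pulses and waves of contractile activity —
ERK-mediated mechanochemical waves, calcium waves, periodic myosin
assembly. `excitissue` implements a minimal mechanical explanation: a
two-dimensional vertex model in which every cell–cell junction is an
excitable unit. A stretched junction activates contractility, stays active
for a period $\tau_{act}$, then passes through a refractory period
$\tau_{ref}$ during which it cannot re-activate, while junction rest
lengths continuously remodel toward their current length at rate $k_L$
(viscoelastic strain relaxation). This stretch–contract–refractory motif,
plus ordinary vertex-model mechanics, is enough to produce quiescent
tissues, solitary traveling pulses, and self-sustained traveling waves —
and geometric disorder in cell packing shifts the balance toward waves.

The package is aimed at researchers in tissue mechanics and excitable
media who want to reproduce and extend these emergent states, sweep their
phase diagrams, and compare against the closed-form predictions of the
accompanying one-dimensional theory.

## The model

Tissue energy over cells $\alpha$ and junctions $\langle i,j\rangle$:

$$H = \frac{K}{2}\sum_\alpha (A_\alpha - A_0)^2 + \Lambda\sum_{\langle i,j\rangle} l_{ij},$$

overdamped vertex dynamics with a length-proportional active tension,

$$\mu\,\dot r_i = -\frac{\partial H}{\partial r_i}
  - \sum_{\langle i,j\rangle} \Gamma_{ij}(t)\, l_{ij}\,\frac{\partial l_{ij}}{\partial r_i},
\qquad \dot l^0_{ij} = -k_L\,(l^0_{ij} - l_{ij}),$$

and the three-state junction automaton: inactive → active when the strain
$\varepsilon_{ij} = (l_{ij}-l^0_{ij})/l^0_{ij}$ reaches
$\varepsilon_{on}$; active ($\Gamma_{ij} = \Gamma_0$) → refractory after
$\tau_{act}$; refractory → inactive after $\tau_{ref}$. T1 neighbor
exchanges fire when a junction drops below $l_{T1}$. The effective
three-junction reduction (`eff_params()`, `simulate_effective()`) admits a
closed-form propagation threshold $\tau_p$ and a reactivation window
$(\tau_1, \tau_2)$ at $k_L = 0$; see the methods vignette
(`vignettes/excitable-tissue-methods.Rmd`) for formulas, numerical choices
and design decisions.

## Worked example

Analytic predictions of the three-junction theory at $\Gamma_0 = 1$,
$\varepsilon_{on} = 0.1$, $k_L = 0$, and a matching simulated outcome:

```r
library(excitissue)
tau_p(1, 0.1)
#> [1] 0.06931472
reactivation_range(1, 0.1)
#>       tau1       tau2
#> 0.07203609 0.16310957
simulate_effective(eff_params(), tau = 0.09, kL = 0, record = FALSE)$label
#> [1] "reactivation"
```

Activity propagates only for activation periods above $\tau_p \approx
0.0693$; within the window $(0.072, 0.163)$ — opening just $0.003$ above
$\tau_p$ — the central junction re-activates when its refractory period
ends, the 1D analogue of a sustained wave. An activation period of $0.09$
falls inside the window, and the simulated model indeed re-activates.

A 2D wave in the 260-cell ordered tissue (single junction activated at the
box center, $\tau = 0.8$, $k_L = 0.7$):

```r
tissue <- make_hexagonal_tissue(260, periodic_box(14, 18.6))
#> box adjusted to commensurate dimensions 13.9694 x 18.6121 (13 cols x 20 rows)
mech  <- mech_params(kL = 0.7)
excit <- excit_params(tau_act = 0.8, tau_ref = 0.8)
seeded <- seed_activation(tissue, "single", NULL, excit)
run_simulation(seeded, mech, excit, t_end = 20)
#> Simulation record: 201 samples to t = 20.00, label 'wave'
#> max active fraction 0.5385, final active fraction 0.4990
```

More than half the junctions are active at the peak and activity persists
to the end of the run: a self-sustained wave. Re-running with `tau_act =
tau_ref = 1.6` instead gives `label 'pulse'` — a single front crosses the
tissue and activity dies — and raising `kL` to 1.5 quenches propagation
entirely (`'quiescent'`). `make_disordered_tissue()`,
`sweep_phase_diagram()`, `critical_kL()` and `measure_wavelength()` cover
the disordered-tissue and wavefront-geometry experiments.

A thin command-line front end is installed at `exec/excitissue`
(subcommands `make-tissue`, `run`, `sweep`, `critical-kl`, `effective`,
`measure`), driven by YAML configurations via `load_config()`.

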