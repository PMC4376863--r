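---
title: "Half-sarcomere mechanics with cross-bridges and a titin filament that binds actin"
author: "sarcomech developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-sarcomere mechanics with cross-bridges and a titin filament that binds actin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sarcomech)
```

## The model

`sarcomech` simulates force generation in a single half sarcomere as the
sum of two coupled sub-models sharing one length clock.

**Active force** comes from a three-state cross-bridge distribution model.
Myosin heads are detached (probability $p_3$), attached pre-power-stroke
(density $p_1(t,x)$ over the cross-bridge link length $x$) or attached and
force-generating ($p_2(t,x)$). The densities obey an advection–reaction
equation, $\partial_t p + v\,\partial_x p = A(x,p)$, where $v$ is the
half-sarcomere sliding velocity (stretch positive) and $A$ collects
attachment, power-stroke and detachment transitions. Active stress is

$$ f_{\mathrm{active}} = S\, g(L) \int \big[\kappa x\, p_1 +
   \kappa (x+\delta)\, p_2\big]\,dx $$

with linear-elastic head force functions (stiffness $\kappa$, power-stroke
offset $\delta$) and a piecewise-linear actin–myosin overlap fraction
$g(L)$ that is 1 on the plateau (2.0–2.4 µm sarcomere length) and 0 at and
beyond 4.0 µm. The published rate surfaces for this model family are not
reproduced here; the defaults (Gaussian attachment kernel near $x=0$, fast
forward power stroke, detachment rising steeply at large strain) are a
qualitatively faithful, fully replaceable parameterisation, and the scale
$S$ is calibrated so that isometric stress at full overlap equals a
configurable reference (150 nN/µm² by default). Quantitative cross-bridge
magnitudes are therefore calibration targets, not predictions.

**Passive force** comes from titin. Each strand spans the half sarcomere
as serial compartments: $N^{prox}$ proximal immunoglobulin (IG) domains
(worm-like chains, folded contour 4.5 nm, gaining 26 nm of contour per
unfolding event), the PEVK segment (an extensible worm-like chain with
stretch modulus $K_0$, contour 0.36 nm per residue), the distal IG domains
aggregated into a rigid end filament, and half the A-band as a very stiff
linear spring. Serial coupling means all compartments carry one common
force; for a given half-sarcomere length the force is the unique root of
the summed inverse force laws (`chain_force()`), found by safeguarded
Newton iteration with an independent bisection oracle used in the tests.
Proximal IG domains unfold stochastically under force with Bell-model
rates $k_i(f) = k_0 e^{f \Delta x_i / k_B T}$ and a weakly hierarchical
barrier-width ladder; refolding never occurs while the strand stays under
load. A Monte-Carlo ensemble (500 strands ≡ 1 µm² of cross-section)
yields stress traces.

**Coupling through actin–titin binding.** On activation the sarcomere
switches to a high-calcium titin parameter set, and titin binds the rigid
actin filament at the most proximal PEVK residue. Binding freezes the
proximal IG compartment at its current length (nearest-binding-site
convention: the event itself generates no force), leaving only the PEVK as
free spring — a much stiffer chain. Because the frozen length records the
proximal extension *at the moment of binding*, force becomes history
dependent: activation at long length freezes a longer proximal segment and
shifts the bound force–length curve rightward. Two activation orderings
("instantaneous calcium" — binding effective at the first ramp after
activation — and "instantaneous binding") and two deactivation extremes
(keep bound / unbind immediately) are provided as `scenario_flags()`.

## Parameters that matter

| parameter | default | units | note |
|---|---|---|---|
| folded IG persistence length | 10 | nm | provisional; calibrate from data |
| unfolded IG persistence length | 0.65 | nm | unfolded polypeptide scale |
| PEVK persistence length | 1.0 | nm | provisional |
| PEVK stretch modulus $K_0$ | 150 | pN | permits extension beyond contour |
| half A-band length $d$ | 800 | nm | thick filament ~1.6 µm |
| distal end filament | 117 | nm | 26 folded domains |
| A-band spring | 1e4 | pN/nm | effectively rigid, finite for smoothness |
| unfolding $k_0$ | 1e-4 | 1/s | zero-force rate |
| barrier widths | 0.25→0.15 | nm | weak hierarchy, domain 1 first |
| calcium force factor | 1.25 | – | see below |
| calcium width multiplier | 0.87 | – | raises unfolding forces ~15% |
| temperature | 293.15 | K | room-temperature experiments |
| ensemble | 500 strands, dt 0.1 ms | | canonical normalization |

The persistence lengths and $K_0$ are the quantities the calibration
module estimates from passive hysteresis loops; the defaults are
literature-scale placeholders chosen once, and all downstream behaviour
(unfolding onset near 120–180 pN, slow passive creep at long lengths)
follows from them.

## Design choices made where the design was open

**Calcium as a uniform force-law scaling.** Physiological calcium raises
titin passive force by about 25%. With the geometry above, a half
sarcomere at 1700 nm with no unfolded domains operates in the PEVK
*enthalpic* regime (extension beyond contour), where force is almost
insensitive to persistence length — scaling persistence lengths alone
cannot deliver a uniform 25%. The high-calcium set therefore scales the
entire titin force law: persistence lengths divided by the calcium factor
and $K_0$ multiplied by it, which raises the chain force by exactly that
factor at every length above slack (and is exactly invertible on
deactivation). The unfolding-force increase under calcium is separate,
implemented as a barrier-width multiplier.

**Rest lengths below slack.** Below the slack length the compartment
lengths are not determined by the physics. The package adopts the
configuration the chain would take at an infinitesimal probe force
(1e-6 pN), which is unique and keeps force traces continuous across the
slack crossing. A consequence worth knowing: at the probe force folded IG
domains extend slightly *more* than unfolded ones (their persistence ×
contour product is larger), so the slack length is essentially the rigid
compartment length and barely changes with the unfolding count.

**Unfolding of bound strands.** After binding, the frozen proximal
segment is mechanically decoupled from the free spring. The force driving
further unfolding of those protected domains is the internal equal force
that stretches the segment to its frozen length — typically a few pN, so
bound strands effectively stop unfolding. This protection is what makes
passive force enhancement positive even when titin unbinds immediately at
deactivation: the passive control keeps creeping (unfolding) at ~60 pN
while the trial's proximal domains were protected, so the trial ends up
stiffer at the same length.

**Event-driven holds.** During ramps the unfolding ensemble is advanced
with the fixed-step Bernoulli scheme in lockstep with the PDE clock.
During constant-length holds, forces are constant between unfolding
events, and the same process is sampled exactly with exponential waiting
times (for a piecewise-constant hazard both schemes give
$P(\text{no event in } m \text{ steps}) = e^{-k m \Delta t}$), making
two-minute steady-state holds cost a handful of events instead of a
million steps.

**Hysteresis-loop classification.** Passive stretch–shorten loops are
split into four regions (pre-unfolding stretch / unfolding stretch / early
shortening / clean late shortening). A curvature (Savitzky–Golay second
derivative) detector was evaluated first and is retained in the package,
but it is nearly blind to the *step-like* force drops a small ensemble
produces (a step's second-difference response is ~1% of the step height).
The default detector is model-based instead: the zero-unfolding chain
model is fitted to an expanding front window of the stretch limb, and the
onset is the first sample falling more than max(3.5 noise SD, 6%) below
the one-step model prediction, confirmed over three samples. The
region-3/4 boundary uses a trend-corrected first-difference detector
scanned backwards from the clean shortening tail. Region 3 (indefinite,
possibly still unfolding) is excluded from all fits.

**Fitting.** Region 1 identifies the folded-IG persistence length and the
PEVK persistence length and modulus by Levenberg–Marquardt least squares
(implemented in the package, log-parameterised, five jittered starts,
relative residuals because the noise is multiplicative). Region 4
identifies the frozen unfolded count by exhaustive integer scan with an
inner one-dimensional optimisation of the unfolded persistence length. An
identifiability caveat established by Fisher-information analysis: at 2%
multiplicative noise and ~40–60 region-1 samples the folded-IG
persistence length carries an irreducible ~15% standard error however
good the optimiser, while the PEVK parameters and the integer count are
sharply identified. Recovery checks should therefore judge that one
parameter across replicate datasets (its median), not per dataset.

## What the synthetic data emulate — and what they do not

`synthesize_hysteresis()` plays the role of myofibril passive hysteresis
measurements: a passive stretch–shorten cycle at 100 nm/s per sarcomere
length, 2.4 → 3.8 → 2.4 µm, sampled to ~100 points with 2% multiplicative
Gaussian noise. By default it simulates a *single* strand so the
shortening limb has a well-defined integer unfolding count (the quantity
the region-4 fit recovers exactly). Real myofibrils average thousands of
strands — their loops are smoother, their unfolding count is an effective
ensemble mean, and their noise is not purely multiplicative. A green
recovery test therefore establishes that the estimator inverts the
package's own generative model at realistic noise; it does not establish
accuracy on tissue data with drift, compliance artefacts or sarcomere
non-uniformity (multi-sarcomere non-uniformity is out of scope entirely).

## Numerical choices

* Chain solve: warm-started Newton on the common force with analytic
  Jacobian, bracketed bisection fallback; tolerance 1e-10 relative on
  length. Matches an independent bisection oracle to <1e-6.
* WLC shape inversion: safeguarded Newton on the interpolation formula,
  1e-14 tolerance; the extensible WLC inverse is closed-form modulo it.
* PDE: first-order upwind advection + explicit Euler reaction,
  CFL-substepped; probability conserved to 1e-6 over whole protocols by
  using one rectangle quadrature for both the attached integral and the
  detached pool, and a strain grid wide enough (−22 to 26 nm) that
  boundary outflow is negligible at protocol velocities.
* Steady-state detection: total-stress drift < 0.1% over a trailing 1 s
  window. With the default unfolding kinetics, unbound titin at long
  lengths creeps quasi-logarithmically, so canonical protocols hold 120 s
  after ramps (well beyond the required 10 s) before the gate passes.
* Rupture: a run stops, with an event logged, when any strand exceeds a
  configurable 600 pN — the stand-in for "the first protein structures
  break" during beyond-overlap stretches; no breakage mechanics are
  modelled.
* Reproducibility: one integer seed drives all randomness; identical
  seeds give byte-identical traces.

## Known limitations

Single half sarcomere only (no inter-sarcomere non-uniformity or
intermyofibrillar links); no actin–titin attachment/detachment kinetics
(the two scenario orderings bracket them); cross-bridge rate surfaces are
stand-ins calibrated at one reference stress; unfolding parameters are
provisional pending calibration against real loop data; below-slack
segment lengths follow a stated convention, not measurements.
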