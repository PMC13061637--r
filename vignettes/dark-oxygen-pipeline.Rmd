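---
title: "From optode traces to dark oxygen production: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From optode traces to dark oxygen production: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkoxygen)
```

## The problem

Sealed benthic chamber landers enclose a patch of abyssal sediment plus its
overlying water and log dissolved O~2~ while the community respires. Over
polymetallic nodule fields the expected signal is a slow decline (sediment
community oxygen consumption, SCOC); the surprising alternative is a rise —
net dark oxygen production (DOP) with no light and no photosynthesis. Deciding
between the two, and defending a rise against mundane explanations, is an
exercise in careful measurement-chain analysis: optode calibration and drift,
dilution artifacts from syringe sampling, O~2~ leaking from the chamber
plastic or trapped bubbles, radiolytic O~2~ from natural radionuclides, and
finally the electrochemical plausibility of seawater electrolysis on nodule
surfaces. This package implements that whole chain, with a synthetic-data
generator standing in for cruise data so every stage is testable end to end.

## The chamber model and its generator

A sealed chamber of footprint $A$ (cm^2^) and water height $h$ (cm) converts
an areal net rate $r = r_\mathrm{DOP} - r_\mathrm{SCOC}$ (mmol m^-2^ d^-1^)
into a volumetric concentration trend

$$\frac{dC}{dt} = \frac{r}{h/100} \quad [\mu\mathrm{mol\,l^{-1}\,d^{-1}}],$$

so 5 mmol m^-2^ d^-1^ over 10 cm of water is 50 µmol l^-1^ d^-1^. The
generator (`simulate_chamber_series()`) layers onto this trend the features
field series actually show:

* **Initial condition.** Starting O~2~ drawn from 185.2 ± 2.9 µmol l^-1^
  (mean ± between-chamber SD), the ambient bottom-water level.
* **Stirrer-off window.** For the first one to two hours the stirrers are off
  so injected substrates can settle; the optode sees a flat trace and the
  generator produces nothing during this window.
* **Saturating production.** Observed production is nonlinear — fast early,
  slowing later — so the instantaneous net rate decays exponentially with a
  single shape parameter $s$ (d^-1^): cumulative production
  $r_0(1-e^{-st})/s$. Any smooth monotone damping would be defensible; the
  exponential form was chosen because it adds exactly one parameter and has
  an interpretable asymptote $r_0/s$. With $s = 0$ the trend is strictly
  linear, which is the configuration parameter-recovery tests use.
* **Syringe dilution.** Each syringe sampling entrains ~50 ml of outside
  seawater, instantaneously mixing the chamber to
  $C' = (C(V-v) + C_a v)/V$. Dips at 28, 38 and 47 h are the default.
* **Sensor noise and drift.** Additive iid Gaussian noise (0.5 µmol l^-1^)
  and a linear drift (0.27 µmol l^-1^ d^-1^, the field drift estimate). The
  true noise spectrum of the instrument is uncharacterized; iid Gaussian is
  an explicit assumption.
* **Logging gaps.** Samples inside configured windows are removed, not
  interpolated, mirroring an optode that intermittently fails to log.

Randomness uses one root seed with per-stream derived seeds
(`derive_seed()`), so the initial-condition draw and the noise vector come
from independent streams and identical configurations are bit-identical.

## Flux estimation choices

`net_o2_change()` reports the total net change
$\Delta C \times V$ from the difference between the maximum and the initial
concentration. Choices the source protocol leaves open:

* **Initial value** = median over the first 5 minutes after sealing (robust
  to single-sample noise; the window length is this package's choice).
* **Rate denominator** = time-to-maximum minus the stirrer-off window. While
  stirring is off nothing is produced (and the optode is not seeing mixed
  water anyway), so excluding it is what makes round-trip recovery of the
  generating rate exact. A least-squares regression rate over the stirred,
  sealed segment is emitted alongside the max-based rate; under saturating
  production both are time averages, not the initial rate.
* **Dilution correction** is available (`correct_dilution()`) but OFF for
  headline results, matching the field treatment of the dips as minor. The
  correction inverts the mass balance per event using the first post-event
  sample and applies cumulative additive shifts; each event's step is
  estimated from the raw series, because later dilutions acted on the
  still-diluted trajectory. On noise-free series the correction is exact to
  machine precision.
* **Volume-unknown chambers** (doors failed to shut) keep their
  concentration-only results and are flagged, never silently dropped or
  imputed.

## Microprofiles and Fick's first law

Porewater O~2~ microprofiles give the diffusive uptake
$J = \varphi D_s\, dC/dz$. With $D_s$ in cm^2^ s^-1^ and the gradient in
µmol l^-1^ mm^-1^, $J$ in mmol m^-2^ d^-1^ carries a unit factor of 8640.
Implementation decisions:

* **Replicate averaging.** The instrument records five readings per depth;
  `average_replicates()` takes the per-depth mean, keeps the replicate SD
  for QC and flags shortfalls. This averaging is why a 0.5 mm gradient
  window suffices at realistic noise.
* **Interface detection.** The field procedure picks the sediment surface
  manually at the turning point where O~2~ begins depleting.
  `detect_surface()` operationalizes this as a grid-search two-segment
  least-squares fit — a constant overlying-water segment joined continuously
  to a linear depletion segment — choosing the breakpoint with minimum
  residual sum of squares. This is equivalent in intent to locating the
  extremum of the smoothed second difference but markedly more robust at
  low signal-to-noise. Manual override is supported
  (`scoc_fick(surface_index = ...)`).
* **Gradient window** defaults to 0.5 mm (10 points at the instrument's
  0.05 mm step) just below the interface.
* **Diffusivity.** $D_0$ for O~2~ at 1.6 °C, S = 35 is pinned at
  1.18e-5 cm^2^ s^-1^ (interpolated from the Schulz & Zabel seawater
  tabulation); the tortuosity correction defaults to Boudreau's
  $D_s = D_0/(1-\ln\varphi^2)$ with an Archie-type power law selectable.
  Porosity has no claimed default — it is a required user input.
* **Generator geometry.** In steady state the oxic-zone depth is not a free
  parameter: it follows from the flux, porosity, diffusivity and overlying
  concentration. The profile generator therefore builds an exactly linear
  near-surface zone (down to $C_0/2$) continued by a slope-continuous
  quadratic roll-off to zero, and derives the zone extents; the configured
  `max_depth_below_surface` only caps how deep the recorded profile goes.
  This construction is what makes noise-free flux recovery exact rather
  than approximate.

## Radiolytic oxygen

Radiolytic O~2~ from a radionuclide inventory follows the kinetic
expression

$$\mathrm{O_2}(t) = Q_{iz}\, E_a\, G(\mathrm{O_2})\, M_{\mathrm{O_2}}\,
A_{iz}^{-1} \times 10^{-2} \times (1 - e^{-\lambda t}),$$

with $Q_{iz}$ the isotope mass (g) in the compartment, $E_a$ the average
energy per decay (eV), $G$ the yield in molecules per 100 eV (the $10^{-2}$
is that normalization), $A_{iz}$ the atomic mass and $\lambda$ the decay
constant. Avogadro's number cancels; the output is in **grams** — the
expression as printed is dimensionally consistent in grams, and unit
conversion happens at the boundary. `decayed_fraction()` uses `expm1`
because $\lambda t \sim 10^{-13}$ over a 48-h incubation and the naive
`1 - exp()` loses three digits there. The tests pin the implementation
against an explicit Avogadro-carrying oracle to 1e-12 relative.

$E_a$ defaults should assume secular equilibrium with the full decay chain
(chain-inclusive energies; configurable to parent-only); $G$ values are
configuration inputs with literature-order defaults. Sediment radiolytic
O~2~ is half a measured H~2~ production rate (2:1 water-splitting
stoichiometry), flagged as a probable overestimate. The full 32-reaction
radiolysis network behind published yield models is deliberately out of
scope — only the summary expression is implemented.

The packaged inventory table (`isotope_inventory_synthetic.csv`) is
**synthetic**: masses assembled from literature-order seawater and nodule
concentrations for a ~4.8 l chamber holding ~1.7 kg of nodules. It exists so
the worked examples and the acceptance script have deterministic inputs; it
does not reproduce any specific published chamber estimate, and its 48-h
output (~3.5e-6 µmol l^-1^) should be read only as "orders of magnitude
below the DOP signal".

## Artifact screening

* **Chamber plastic.** The intrusion bound scales a cited reference release
  (20.66 µmol l^-1^ out of 428 cm^2^ of polyoxymethylene in 48 h) linearly
  in exposed area and duration. Exposed area is lid + four wetted wall
  strips; water depths of 4.375–12.5 cm give 869–1584 cm^2^ and bounds of
  41.9–76.5 µmol l^-1^ per 48 h. Scaling the concentration release (rather
  than recomputing from the 0.02 µmol cm^-2^ d^-1^ rate) is the mode that
  reproduces those endpoints exactly; the rate route is kept as a
  cross-check mode.
* **Core-tube leaks.** `leak_percent(0.14, 3.5)` gives 4.0% — the shipboard
  control. The laboratory control (0.11 against 3.5) computes to 3.14%;
  where a printed 3.2% differs from the arithmetic, this package reports
  the arithmetic.
* **Bubbles.** `bubble_dissolution_time()` is a declared quasi-static
  Epstein–Plesset-type model: gas at hydrostatic + atmospheric pressure,
  pressure-proportional interfacial solubility, $t = \rho_g R^2/(2D\Delta C)$.
  Its testable properties are the $R^2$ scaling and strict decrease with
  depth. For millimetre bubbles at 4000 m it gives hours, not sub-second —
  unsurprising, since sub-second figures depend on model inputs not
  published alongside the claim. The screening report therefore treats the
  bubble timescale as advisory and rests the bubble argument on the physics
  that matters: a dissolving bubble is a transient, inconsistent with
  steady multi-hour production.

## Electrochemistry and statistics

The thermodynamic water-splitting potential is $|\Delta G^\circ|/(nF)$ =
237.1 kJ mol^-1^ / (2 × 96485 C mol^-1^) = 1.229 V; the oxygen evolution
reaction additionally needs an overpotential (default 0.37 V), reducible by
a configurable amount under the lattice-oxygen-mediated mechanism.
Feasibility uses an inclusive boundary (observed max ≥ required).

Survey summaries use Tukey hinges (`fivenum`) for the quartiles — the
"excluding the median" convention of the field figures — with whiskers at
the extremes and the mean marked separately. One-way ANOVA is the classical
decomposition (via `lm`), reported as F(df1, df2) with the degenerate
all-identical case defined as F = 0, p = 1. Spearman correlations use
average ranks; the two-sided p-value is an exhaustive permutation
enumeration for n ≤ 9 (exact even under ties, 9! = 362,880 permutations)
and the t approximation above that. The switch point is documented, not
silent: `spearman_correlation()` reports which method produced its p.

## What the synthetic campaign does and does not show

The generator reproduces the *statistical structure* of the field data:
initial levels, saturating rises with maxima inside the observed envelope,
dilution dips of exactly mass-balance size, stirrer-off plateaus, drift,
noise, gaps, replicate microprofile readings, background-offset voltage
surveys, compositional taxon tables with a rank-correlated taxon. Passing
tests therefore demonstrate that the estimators are unbiased and correctly
scaled *under the generating model* — they cannot validate the generating
model itself against instrument physics (optode phase dynamics, chamber
hydrodynamics, correlated sensor noise), and no synthetic result bears on
whether DOP occurs in nature.

Problem sizes used throughout (chosen as comfortable for the statistical
checks, and stated here for reproducibility): 25-chamber ensembles at 10-s
logging over 47 h for campaign emulation, 100-seed Monte-Carlo loops for
parameter-recovery and interface-detection properties, 541-point
microprofiles at 0.05 mm steps with 5 replicates per depth.

## Known limitations

* The optode raw-signal model is affine per temperature with linear
  interpolation of coefficients — a two-point abstraction that is exact at
  the calibration points but is not the proprietary phase-based
  (Stern–Volmer) transfer function of real sensors.
* Whether field Winkler-optode offsets were computed against
  drift-corrected optode values is unknown; drift correction here defaults
  to off.
* The bubble model and the radiolysis inventory are declared stand-ins for
  unpublished counterparts, as flagged above.
* No hydrodynamic chamber mixing, no diffusive-boundary-layer flux, no
  reaction–diffusion modelling of O~2~ penetration, and no upscaling of DOP
  rates beyond a chamber — the variance between chambers argues against
  naive spatial or temporal extrapolation.
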